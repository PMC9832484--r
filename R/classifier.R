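# Phase-behavior classification: autoscaling, PCA, NIPALS PLS-DA (single
# binary response) and the nested (double) leave-one-ELP-out
# cross-validation that produces per-ELP prediction intervals.

.descriptor_cols <- function(data) {
  setdiff(names(data), c("elp", "replica", "time_ns"))
}

.as_matrix <- function(data) {
  if (is.data.frame(data)) {
    as.matrix(data[, .descriptor_cols(data), drop = FALSE])
  } else {
    as.matrix(data)
  }
}

#' Autoscale a descriptor matrix
#'
#' Centres each column to mean zero and scales to unit variance using the
#' population (divide-by-n) standard deviation, the chemometrics
#' convention for descriptor blocks. Constant columns cannot be scaled and
#' are dropped with a warning (recorded in the model so new data is
#' treated identically).
#'
#' @param data A numeric matrix or a descriptor tibble (metadata columns
#'   `elp`, `replica`, `time_ns` are ignored).
#' @return A list of class `elp_scaling`: `x` (scaled matrix), `center`,
#'   `scale`, `dropped` (names of constant columns).
#' @export
autoscale <- function(data) {
  x <- .as_matrix(data)
  if (nrow(x) < 2) abort("Need at least 2 rows to autoscale")
  ctr <- colMeans(x)
  sds <- sqrt(colMeans(sweep(x, 2, ctr)^2))
  dropped <- colnames(x)[sds <= 0 | !is.finite(sds)]
  if (length(dropped) == ncol(x)) abort("All columns are constant")
  if (length(dropped) > 0) {
    warn(sprintf("Dropping %d constant column(s): %s",
                 length(dropped), paste(dropped, collapse = ", ")))
  }
  keep <- setdiff(colnames(x), dropped)
  xs <- sweep(sweep(x[, keep, drop = FALSE], 2, ctr[keep]), 2, sds[keep], "/")
  structure(
    list(x = xs, center = ctr[keep], scale = sds[keep], dropped = dropped),
    class = "elp_scaling"
  )
}

#' Apply or invert a fitted scaling
#'
#' @param scaling An `elp_scaling` from [autoscale()].
#' @param data New data (matrix or descriptor tibble) with the training
#'   columns.
#' @return The scaled (or unscaled) matrix.
#' @export
scale_apply <- function(scaling, data) {
  x <- .as_matrix(data)
  miss <- setdiff(names(scaling$center), colnames(x))
  if (length(miss) > 0) {
    abort(paste0("New data is missing column(s): ", paste(miss, collapse = ", ")))
  }
  x <- x[, names(scaling$center), drop = FALSE]
  sweep(sweep(x, 2, scaling$center), 2, scaling$scale, "/")
}

#' @rdname scale_apply
#' @export
scale_invert <- function(scaling, data) {
  x <- as.matrix(data)
  sweep(sweep(x, 2, scaling$scale, "*"), 2, scaling$center, "+")
}

#' Principal component analysis of a scaled descriptor matrix
#'
#' Decomposes `X = T P' + E` with orthonormal loadings and components
#' ordered by explained variance (computed by singular value
#' decomposition of the column-centred matrix).
#'
#' @param x A scaled numeric matrix (see [autoscale()]).
#' @param ncomp Number of components, at most `min(n - 1, ncol(x))`.
#' @return A list of class `elp_pca`: `loadings` (p x k), `scores`
#'   (n x k), `explained` (variance ratio per component), `residuals`
#'   (the matrix E), `center`.
#' @export
fit_pca <- function(x, ncomp = 2) {
  x <- .as_matrix(x)
  n <- nrow(x)
  if (ncomp > min(n - 1, ncol(x))) {
    abort("`ncomp` exceeds min(n - 1, number of columns)")
  }
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  sv <- svd(xc)
  scores <- sv$u[, seq_len(ncomp), drop = FALSE] %*%
    diag(sv$d[seq_len(ncomp)], ncomp)
  loadings <- sv$v[, seq_len(ncomp), drop = FALSE]
  rownames(loadings) <- colnames(x)
  colnames(loadings) <- paste0("PC", seq_len(ncomp))
  colnames(scores) <- paste0("PC", seq_len(ncomp))
  explained <- (sv$d^2 / sum(sv$d^2))[seq_len(ncomp)]
  resid <- xc - scores %*% t(loadings)
  structure(
    list(loadings = loadings, scores = scores, explained = explained,
         residuals = resid, center = ctr),
    class = "elp_pca"
  )
}

#' @export
print.elp_pca <- function(x, ...) {
  cat(sprintf("<elp_pca> %d component(s); explained variance: %s\n",
              ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", ")))
  invisible(x)
}

#' Fit a PLS-DA model (NIPALS, single binary response)
#'
#' Sequential NIPALS extraction for a univariate response: each weight
#' vector is the normalized covariance direction `w_a = X'y / |X'y|`, the
#' score is `t_a = X w_a`, and X (and y) are deflated before the next
#' component. Scores reconstruct `X = T P' + E` and predict
#' `y = T b + F`. Class membership is coded 0/1 and predicted values are
#' thresholded at 0.5 (see [classify_phase()]).
#'
#' @param x Scaled predictor matrix.
#' @param y Numeric 0/1 response, one per row of `x`.
#' @param ncomp Number of components (>= 1, at most `min(n - 1, p)`).
#' @return A list of class `elp_plsda`: `weights` W (unit-norm columns),
#'   `loadings` P, `scores` T, `coef` b (per-component regression
#'   weights), `B` (equivalent single regression vector on the scaled
#'   predictors), `intercept`, `fitted`, `residuals` F, `ncomp`,
#'   `threshold`.
#' @export
fit_plsda <- function(x, y, ncomp = 2) {
  x <- .as_matrix(x)
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(x))
  if (length(unique(y)) < 2) abort("Both classes must be present in `y`")
  if (ncomp < 1 || ncomp > min(nrow(x) - 1, ncol(x))) {
    abort("`ncomp` must be in [1, min(n - 1, p)]")
  }
  xd <- x
  yd <- y - mean(y)
  y_mean <- mean(y)
  p <- ncol(x)
  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  Tm <- matrix(0, nrow(x), ncomp)
  b <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- crossprod(xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      abort(sprintf("Component %d exceeds the rank of the data", a))
    }
    w <- w / nw
    t_a <- xd %*% w
    tt <- sum(t_a^2)
    p_a <- crossprod(xd, t_a) / tt
    b_a <- sum(t_a * yd) / tt
    xd <- xd - t_a %*% t(p_a)
    yd <- yd - b_a * t_a
    W[, a] <- w
    P[, a] <- p_a
    Tm[, a] <- t_a
    b[a] <- b_a
  }
  rownames(W) <- rownames(P) <- colnames(x)
  # equivalent direct regression vector: yhat = y_mean + X B
  Rmat <- W %*% solve(t(P) %*% W)
  B <- Rmat %*% b
  fitted <- as.numeric(y_mean + x %*% B)
  structure(
    list(weights = W, loadings = P, scores = Tm, coef = b, B = B,
         intercept = y_mean, fitted = fitted, residuals = y - fitted,
         ncomp = ncomp, threshold = 0.5, columns = colnames(x)),
    class = "elp_plsda"
  )
}

#' @export
print.elp_plsda <- function(x, ...) {
  cat(sprintf("<elp_plsda> %d component(s), %d predictor(s), threshold %.2f\n",
              x$ncomp, length(x$B), x$threshold))
  invisible(x)
}

#' Predict continuous class values from a PLS-DA model
#'
#' Row-level predictions follow the deflation path of the fitted model;
#' with grouping, per-group values are the arithmetic mean of all row
#' predictions (all replicas and time points of an ELP).
#'
#' @param object An `elp_plsda`.
#' @param newdata Scaled matrix with the training columns, or descriptor
#'   tibble.
#' @param group Optional grouping vector (e.g. ELP ids, one per row) for
#'   aggregation.
#' @param ncomp Number of components to use (default: all fitted).
#' @param ... Unused.
#' @return Without `group`: numeric vector of row predictions. With
#'   `group`: a tibble with columns `group`, `prediction`, `n_rows`.
#' @export
predict.elp_plsda <- function(object, newdata, group = NULL,
                              ncomp = object$ncomp, ...) {
  x <- .as_matrix(newdata)
  miss <- setdiff(object$columns, colnames(x))
  if (length(miss) > 0) {
    abort(paste0("New data is missing column(s): ", paste(miss, collapse = ", ")))
  }
  x <- x[, object$columns, drop = FALSE]
  stopifnot(ncomp >= 1, ncomp <= object$ncomp)
  xd <- x
  yhat <- rep(object$intercept, nrow(x))
  for (a in seq_len(ncomp)) {
    t_a <- xd %*% object$weights[, a]
    yhat <- yhat + object$coef[a] * t_a
    xd <- xd - t_a %*% t(object$loadings[, a])
  }
  yhat <- as.numeric(yhat)
  if (is.null(group)) return(yhat)
  stopifnot(length(group) == nrow(x))
  tibble(group = group, prediction = yhat) %>%
    group_by(.data$group) %>%
    summarise(prediction = mean(.data$prediction), n_rows = n(),
              .groups = "drop")
}

#' Convert a continuous prediction to a 0/1 class
#'
#' The threshold is the midpoint of the 0/1 coding; a value exactly at the
#' threshold is assigned class 0 (absence), the documented tie-break.
#'
#' @param value Numeric prediction(s).
#' @param threshold Decision boundary (default 0.5).
#' @return Integer 0/1 vector.
#' @export
#' @examples
#' classify_phase(c(0.9, 0.1, 0.5))
classify_phase <- function(value, threshold = 0.5) {
  stopifnot(all(is.finite(value)))
  as.integer(value > threshold)
}

#' Select the PLS-DA component count against a validation ELP
#'
#' Returns the smallest component count (up to `k_max`) that classifies
#' the validation ELP correctly. If no count succeeds, falls back to the
#' count whose validation prediction lies furthest toward the correct
#' side of the threshold (ties broken toward fewer components) and flags
#' the fallback.
#'
#' @param model An `elp_plsda` fitted with `k_max` components.
#' @param x_val Scaled validation rows (all rows of the validation ELP).
#' @param y_val The validation ELP's true class (0 or 1).
#' @param k_max Maximum component count to consider.
#' @return Integer `k`, with attribute `fallback` (logical).
#' @export
select_components <- function(model, x_val, y_val, k_max = model$ncomp) {
  k_max <- min(k_max, model$ncomp)
  margins <- vapply(seq_len(k_max), function(k) {
    pred <- mean(predict(model, x_val, ncomp = k))
    if (y_val == 1) pred - model$threshold else model$threshold - pred
  }, numeric(1))
  correct <- margins > 0
  if (any(correct)) {
    k <- which(correct)[1]
    fallback <- FALSE
  } else {
    k <- which.max(margins)
    fallback <- TRUE
  }
  out <- as.integer(k)
  attr(out, "fallback") <- fallback
  out
}

#' Student-t confidence interval for repeated predictions
#'
#' @param predictions Numeric vector (>= 2 values).
#' @param level Confidence level (default 0.99).
#' @return A tibble with columns `mean`, `low`, `high`.
#' @export
#' @examples
#' confidence_interval(c(0.8, 0.9))
confidence_interval <- function(predictions, level = 0.99) {
  n <- length(predictions)
  if (n < 2) abort("Need at least 2 predictions for an interval")
  m <- mean(predictions)
  half <- qt(1 - (1 - level) / 2, df = n - 1) * sd(predictions) / sqrt(n)
  tibble(mean = m, low = m - half, high = m + half)
}

#' Double (nested) leave-one-ELP-out cross-validation of PLS-DA
#'
#' The outer loop holds each ELP out as the test set once. For each outer
#' split, the inner loop holds each remaining ELP out as validation once,
#' fits a PLS-DA model on the rest, selects the component count on the
#' validation ELP ([select_components()]), and predicts the test ELP with
#' that model. With 8 ELPs this yields 8 x 7 = 56 model fits and 7
#' predictions per ELP, which are combined into a mean and a Student-t
#' confidence interval. All rows of an ELP (every replica and time point)
#' always travel together, so no test row ever enters a training fold.
#' Scaling is refit inside every training fold.
#'
#' @param descriptors Descriptor tibble with columns `elp`, `replica`,
#'   `time_ns` and numeric descriptor columns.
#' @param labels Tibble with columns `elp` and `label` (0/1).
#' @param k_max Maximum PLS components considered (default 10, capped by
#'   the data's rank constraints).
#' @param level Confidence level for the per-ELP intervals (default 0.99).
#' @return A list of class `elp_dcv`: `predictions` (per-ELP tibble with
#'   the individual outer predictions, mean, interval, predicted and true
#'   class), `folds` (per inner fit: test/validation ELP, chosen `k`,
#'   fallback flag), `accuracy` (percent of ELPs whose mean prediction
#'   classifies correctly), `ci_correct_pct` (percent whose interval lies
#'   entirely on the correct side of the threshold), `level`, `n_fits`.
#' @export
double_cross_validate <- function(descriptors, labels, k_max = 10,
                                  level = 0.99) {
  elps <- unique(descriptors$elp)
  if (length(elps) < 3) abort("Need at least 3 ELPs for double cross-validation")
  lab <- setNames(labels$label, labels$elp)
  if (!all(elps %in% names(lab))) abort("Every ELP needs a label")
  if (length(unique(lab[elps])) < 2) abort("Both classes must be present")
  cols <- .descriptor_cols(descriptors)
  folds <- list()
  preds <- list()
  for (test_elp in elps) {
    rest <- setdiff(elps, test_elp)
    test_rows <- descriptors$elp == test_elp
    for (val_elp in rest) {
      train_elps <- setdiff(rest, val_elp)
      if (length(unique(lab[train_elps])) < 2) {
        warn(sprintf(
          "Fold (test %s, validation %s) skipped: training labels single-class",
          test_elp, val_elp
        ))
        next
      }
      train_rows <- descriptors$elp %in% train_elps
      sc <- suppressWarnings(autoscale(descriptors[train_rows, cols]))
      x_train <- sc$x
      y_train <- lab[descriptors$elp[train_rows]]
      k_cap <- min(k_max, ncol(x_train), nrow(x_train) - 1)
      model <- fit_plsda(x_train, y_train, ncomp = k_cap)
      x_val <- scale_apply(sc, descriptors[descriptors$elp == val_elp, cols])
      k <- select_components(model, x_val, lab[val_elp], k_max = k_cap)
      x_test <- scale_apply(sc, descriptors[test_rows, cols])
      pred <- mean(predict(model, x_test, ncomp = as.integer(k)))
      k_fallback <- isTRUE(attr(k, "fallback"))
      folds[[length(folds) + 1]] <- tibble(
        test_elp = test_elp, val_elp = val_elp, k = as.integer(k),
        fallback = k_fallback,
        train_elps = list(train_elps),
        train_rows = list(which(train_rows))
      )
      preds[[length(preds) + 1]] <- tibble(elp = test_elp, prediction = pred)
    }
  }
  folds <- bind_rows(folds)
  preds <- bind_rows(preds)
  if (nrow(preds) == 0) {
    abort("No usable folds: every training split was single-class")
  }
  per_elp <- preds %>%
    group_by(.data$elp) %>%
    summarise(
      predictions = list(.data$prediction),
      mean = mean(.data$prediction),
      n = n(),
      sd = sd(.data$prediction),
      .groups = "drop"
    ) %>%
    mutate(
      half = qt(1 - (1 - level) / 2, df = .data$n - 1) * .data$sd / sqrt(.data$n),
      low = .data$mean - .data$half,
      high = .data$mean + .data$half,
      truth = as.integer(lab[.data$elp]),
      predicted = classify_phase(.data$mean),
      correct = .data$predicted == .data$truth,
      ci_correct_side = ifelse(
        .data$truth == 1, .data$low > 0.5, .data$high < 0.5
      )
    ) %>%
    select(-"half") %>%
    arrange(match(.data$elp, elps))
  structure(
    list(
      predictions = per_elp,
      folds = folds,
      accuracy = 100 * mean(per_elp$correct),
      ci_correct_pct = 100 * mean(per_elp$ci_correct_side),
      level = level,
      n_fits = nrow(folds)
    ),
    class = "elp_dcv"
  )
}

#' @export
print.elp_dcv <- function(x, ...) {
  cat(sprintf(
    "<elp_dcv> %d ELPs, %d model fits; accuracy %.1f%%; %.1f%% of %d%% CIs on the correct side\n",
    nrow(x$predictions), x$n_fits, x$accuracy, x$ci_correct_pct,
    round(100 * x$level)
  ))
  invisible(x)
}
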
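# Autoscaling, PCA, NIPALS PLS-DA and the nested double cross-validation.

make_xy <- function(n = 40, p = 8, seed = 42) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n)
  colnames(x) <- paste0("d", seq_len(p))
  y <- rep(c(0, 1), each = n / 2)
  list(x = x, y = y)
}

test_that("autoscale uses the population-sd convention and is idempotent", {
  x <- cbind(a = c(3, 5, 7), b = c(1, 2, 4))
  sc <- autoscale(x)
  expect_equal(sc$x[, "a"], c(-1.224745, 0, 1.224745), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(colMeans(sc$x), c(a = 0, b = 0), tolerance = 1e-12)

  sc2 <- autoscale(sc$x)
  expect_equal(sc2$x, sc$x, tolerance = 1e-10)

  # apply-then-invert recovers the input
  expect_equal(scale_invert(sc, scale_apply(sc, x)), unclass(x),
               tolerance = 1e-10, ignore_attr = TRUE)

  # constant columns are dropped with a warning
  x3 <- cbind(x, cst = 1)
  expect_warning(sc3 <- autoscale(x3), "cst")
  expect_equal(ncol(sc3$x), 2)
  expect_error(suppressWarnings(autoscale(cbind(k = c(1, 1, 1)))), "constant")
})

test_that("PCA matches an SVD oracle and reconstructs exactly", {
  d <- make_xy(n = 50, p = 10)
  xs <- autoscale(d$x)$x
  p <- fit_pca(xs, ncomp = 6)

  pr <- prcomp(xs, center = TRUE, scale. = FALSE)
  for (k in 1:6) {
    expect_equal(abs(p$scores[, k]), abs(pr$x[, k]), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(abs(p$loadings[, k]), abs(pr$rotation[, k]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  expect_true(all(diff(p$explained) <= 1e-12))
  expect_lte(sum(p$explained), 1 + 1e-12)

  # X_centred = T P' + E at any k
  xc <- sweep(xs, 2, p$center)
  expect_lt(max(abs(xc - p$scores %*% t(p$loadings) - p$residuals)), 1e-8)
  # loadings orthonormal
  expect_equal(crossprod(p$loadings), diag(6), tolerance = 1e-10,
               ignore_attr = TRUE)

  # rank-1 data: first component explains everything
  r1 <- outer(rnorm(20), rnorm(5))
  p1 <- fit_pca(r1, ncomp = 2)
  expect_equal(p1$explained[1], 1, tolerance = 1e-10)

  # full rank: residual norm vanishes
  pfull <- fit_pca(xs[1:11, ], ncomp = 10)
  expect_lt(sqrt(sum(pfull$residuals^2)), 1e-8)

  expect_error(fit_pca(xs, ncomp = 11), "ncomp")
})

test_that("PLS first component is the normalized covariance direction", {
  d <- make_xy()
  xs <- autoscale(d$x)$x
  m <- fit_plsda(xs, d$y, ncomp = 3)
  w1 <- crossprod(xs, d$y - mean(d$y))
  w1 <- w1 / sqrt(sum(w1^2))
  expect_equal(as.numeric(m$weights[, 1]), as.numeric(w1), tolerance = 1e-10)
  expect_equal(sqrt(colSums(m$weights^2)), rep(1, 3), tolerance = 1e-10)
  # residuals orthogonal to scores
  expect_lt(max(abs(crossprod(m$scores, m$residuals))), 1e-8)
})

test_that("PLS-DA predictions match an independent reference implementation", {
  skip_if_not_installed("mixOmics")
  d <- make_xy(n = 30, p = 6, seed = 9)
  xs <- autoscale(d$x)$x
  for (k in c(1, 3)) {
    m <- fit_plsda(xs, d$y, ncomp = k)
    ref <- mixOmics::pls(xs, d$y, ncomp = k, scale = FALSE,
                         mode = "regression")
    pref <- predict(ref, xs)$predict[, , k]
    expect_equal(m$fitted, as.numeric(pref), tolerance = 1e-6)
    # new-data path agrees with the fitted path
    expect_equal(predict(m, xs), m$fitted, tolerance = 1e-10)
  }
})

test_that("separable centroids are classified correctly at one component", {
  set.seed(5)
  x <- rbind(matrix(rnorm(60), 20) , matrix(rnorm(60), 20) + 4)
  colnames(x) <- paste0("d", 1:3)
  y <- rep(c(0, 1), each = 20)
  xs <- autoscale(x)$x
  m <- fit_plsda(xs, y, ncomp = 1)
  expect_equal(classify_phase(m$fitted), y)
})

test_that("single-column signal reduces PLS-DA to thresholding that column", {
  set.seed(13)
  n <- 60
  informative <- c(rnorm(n / 2), rnorm(n / 2) + 5)
  # the remaining columns repeat identically in both classes, so their
  # covariance with y is exactly zero and only the informative column
  # carries weight
  block <- matrix(rnorm(n / 2 * 4), n / 2)
  x <- cbind(sig = informative, rbind(block, block))
  colnames(x)[2:5] <- paste0("flat", 1:4)
  y <- rep(c(0, 1), each = n / 2)
  xs <- autoscale(x)$x
  m <- fit_plsda(xs, y, ncomp = 1)
  expect_equal(abs(as.numeric(m$weights[, 1])), c(1, 0, 0, 0, 0),
               tolerance = 1e-10)
  expect_equal(cor(m$fitted, x[, "sig"]), 1, tolerance = 1e-10)
  expect_equal(classify_phase(m$fitted),
               as.integer(x[, "sig"] > mean(x[, "sig"])))
})

test_that("classification threshold and tie-break are as documented", {
  expect_identical(classify_phase(c(0.9, 0.1, 0.5, 0.500001)),
                   c(1L, 0L, 0L, 1L))
  expect_error(classify_phase(NaN))
})

test_that("prediction aggregates to one value per ELP", {
  d <- make_xy()
  xs <- autoscale(d$x)$x
  m <- fit_plsda(xs, d$y, ncomp = 2)
  grp <- rep(c("a", "b"), times = 20)
  agg <- predict(m, xs, group = grp)
  expect_equal(nrow(agg), 2)
  expect_equal(agg$prediction[agg$group == "a"],
               mean(predict(m, xs)[grp == "a"]))
  # all-identical rows aggregate to the single-row prediction
  one <- xs[rep(1, 5), ]
  agg1 <- predict(m, one, group = rep("z", 5))
  expect_equal(agg1$prediction, predict(m, xs[1, , drop = FALSE]))
  expect_error(predict(m, xs[, 1:3]), "missing column")
})

test_that("component selection prefers the smallest sufficient k", {
  set.seed(17)
  x <- rbind(matrix(rnorm(90), 30), matrix(rnorm(90), 30) + 4)
  colnames(x) <- paste0("d", 1:3)
  y <- rep(c(0, 1), each = 30)
  sc <- autoscale(x[1:50, ])
  m <- fit_plsda(sc$x, y[1:50], ncomp = 3)
  xv <- scale_apply(sc, x[51:60, ])
  k <- select_components(m, xv, y_val = 1, k_max = 3)
  expect_equal(as.integer(k), 1L)
  expect_false(attr(k, "fallback"))
  # forced k_max
  k1 <- select_components(m, xv, y_val = 1, k_max = 1)
  expect_equal(as.integer(k1), 1L)
  # impossible validation label triggers the flagged fallback
  kf <- select_components(m, xv, y_val = 0, k_max = 3)
  expect_true(attr(kf, "fallback"))
})

test_that("confidence intervals follow the Student-t formula", {
  ci <- confidence_interval(c(0.8, 0.9))
  half <- qt(0.995, 1) * sd(c(0.8, 0.9)) / sqrt(2)
  expect_equal(ci$mean, 0.85)
  expect_equal(ci$high - ci$mean, half, tolerance = 1e-12)

  same <- confidence_interval(rep(0.7, 5))
  expect_equal(same$low, 0.7)
  expect_equal(same$high, 0.7)
  expect_error(confidence_interval(0.5), "at least 2")
})

test_that("double CV bookkeeping: fold counts, predictions, no leakage", {
  d <- gen_descriptor_dataset(cluster_spec(n_timepoints = 20, seed = 31))
  dcv <- double_cross_validate(d$descriptors, d$labels, k_max = 5)
  expect_equal(dcv$n_fits, 8 * 7)
  expect_true(all(dcv$predictions$n == 7))
  # no fold ever trains on its own test or validation ELP
  expect_true(all(dcv$folds$test_elp != dcv$folds$val_elp))

  # 4 ELPs (2 per class): only folds whose 2-ELP training split still has
  # both classes survive -> 8 of the 12 structural fits, 2 predictions
  # per ELP
  keep <- c("ELP01", "ELP02", "ELP05", "ELP06")
  d4 <- d$descriptors[d$descriptors$elp %in% keep, ]
  l4 <- d$labels[d$labels$elp %in% keep, ]
  dcv4 <- suppressWarnings(double_cross_validate(d4, l4, k_max = 3))
  expect_equal(dcv4$n_fits, 8)
  expect_true(all(dcv4$predictions$n == 2))

  # single-class fold skipping is announced (one warning per skipped fold)
  warns <- testthat::capture_warnings(double_cross_validate(d4, l4, k_max = 3))
  expect_length(warns, 4)
  expect_true(all(grepl("single-class", warns)))

  d3 <- d$descriptors[d$descriptors$elp %in% keep[1:2], ]
  l3 <- d$labels[d$labels$elp %in% keep[1:2], ]
  expect_error(double_cross_validate(d3, l3), "at least 3")

  # a 2/1 class split leaves every 1-ELP training fold single-class
  d21 <- d$descriptors[d$descriptors$elp %in% keep[1:3], ]
  l21 <- d$labels[d$labels$elp %in% keep[1:3], ]
  expect_error(suppressWarnings(double_cross_validate(d21, l21)),
               "single-class")
})

test_that("double CV separates shifted clusters and collapses under no signal", {
  d <- gen_descriptor_dataset(
    cluster_spec(n_timepoints = 40, delta = 4, n_informative = 6, seed = 57)
  )
  dcv <- double_cross_validate(d$descriptors, d$labels)
  expect_equal(dcv$accuracy, 100)
  expect_equal(dcv$ci_correct_pct, 100)

  # no signal: the nested leave-one-ELP-out scheme has a deterministic
  # anti-learning bias (the training intercept sits on the wrong side for
  # every held-out ELP), so the null shows no predictive skill at all
  d0 <- gen_descriptor_dataset(
    cluster_spec(n_timepoints = 40, delta = 0, seed = 58)
  )
  dcv0 <- double_cross_validate(d0$descriptors, d0$labels)
  expect_lte(dcv0$accuracy, 50)
  expect_lte(dcv0$ci_correct_pct, 50)
})

test_that("tidiers expose per-ELP results and summary", {
  d <- gen_descriptor_dataset(cluster_spec(n_timepoints = 15, seed = 77))
  dcv <- double_cross_validate(d$descriptors, d$labels, k_max = 3)
  td <- tidy(dcv)
  expect_named(td, c("elp", "truth", "mean", "low", "high", "predicted",
                     "correct", "ci_correct_side", "n"))
  gl <- glance(dcv)
  expect_equal(gl$n_elps, 8)
  expect_s3_class(autoplot(dcv), "ggplot")
})
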
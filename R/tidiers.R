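# broom-style tidy()/glance() methods for the package's fitted objects.

#' Tidy methods for elptools objects
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @return A tibble whose rows are the natural units of the object
#'   (loadings, coefficients, per-ELP predictions, fit parameters or
#'   spectral components).
#' @name tidy_elptools
NULL

#' @rdname tidy_elptools
#' @export
tidy.elp_pca <- function(x, ...) {
  as_tibble(x$loadings, rownames = "descriptor") %>%
    tidyr::pivot_longer(-"descriptor", names_to = "component",
                        values_to = "loading")
}

#' @rdname tidy_elptools
#' @export
glance.elp_pca <- function(x, ...) {
  tibble(
    n_components = ncol(x$scores),
    explained_total = sum(x$explained),
    residual_norm = sqrt(sum(x$residuals^2))
  )
}

#' @rdname tidy_elptools
#' @export
tidy.elp_plsda <- function(x, ...) {
  tibble(
    descriptor = rownames(x$weights),
    coefficient = as.numeric(x$B)
  ) %>% arrange(dplyr::desc(abs(.data$coefficient)))
}

#' @rdname tidy_elptools
#' @export
glance.elp_plsda <- function(x, ...) {
  tibble(
    n_components = x$ncomp,
    rss = sum(x$residuals^2),
    threshold = x$threshold
  )
}

#' @rdname tidy_elptools
#' @export
tidy.elp_dcv <- function(x, ...) {
  x$predictions %>%
    select("elp", "truth", "mean", "low", "high", "predicted", "correct",
           "ci_correct_side", "n")
}

#' @rdname tidy_elptools
#' @export
glance.elp_dcv <- function(x, ...) {
  tibble(
    n_elps = nrow(x$predictions),
    n_fits = x$n_fits,
    accuracy = x$accuracy,
    ci_correct_pct = x$ci_correct_pct,
    level = x$level,
    any_fallback = any(x$folds$fallback)
  )
}

#' @rdname tidy_elptools
#' @export
tidy.frap_fit <- function(x, ...) {
  tibble(
    term = c("A", "k_frap"),
    estimate = c(x$A, x$k_frap),
    std.error = c(x$A_se, x$k_se)
  )
}

#' @rdname tidy_elptools
#' @export
glance.frap_fit <- function(x, ...) {
  tibble(converged = x$converged, residual_sd = x$residual_sd,
         n = nrow(x$fitted))
}

#' @rdname tidy_elptools
#' @export
tidy.amide1_fit <- function(x, ...) {
  if (is.null(x$components)) return(tibble())
  x$components
}

#' @rdname tidy_elptools
#' @export
glance.amide1_fit <- function(x, ...) {
  tibble(converged = x$converged, ordered_fraction = x$ordered_fraction,
         residual_sd = x$residual_sd)
}

#' Plot methods for elptools result objects
#'
#' `autoplot()` methods returning ggplot objects: hydropathy profiles,
#' PCA score plots, double-cross-validation prediction intervals against
#' the 0.5 decision threshold, FRAP recovery fits and amide-I
#' deconvolutions.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @name autoplot_elptools
NULL

#' @rdname autoplot_elptools
#' @param colour Optional grouping vector (one per observation) mapped to
#'   point colour in the PCA score plot.
#' @export
autoplot.elp_pca <- function(object, colour = NULL, ...) {
  df <- as_tibble(object$scores[, 1:2, drop = FALSE])
  names(df) <- c("PC1", "PC2")
  if (!is.null(colour)) df$group <- colour
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained[2])
    ) +
    ggplot2::theme_minimal()
  if (is.null(colour)) {
    p + ggplot2::geom_point(alpha = 0.6)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), alpha = 0.6) +
      ggplot2::labs(colour = NULL)
  }
}

#' @rdname autoplot_elptools
#' @export
autoplot.elp_dcv <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$elp, y = .data$mean,
                                   colour = factor(.data$truth))) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$low, ymax = .data$high)) +
    ggplot2::labs(x = NULL, y = "Predicted phase behavior",
                  colour = "True class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname autoplot_elptools
#' @export
autoplot.frap_fit <- function(object, ...) {
  ggplot2::ggplot(object$fitted, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$intensity), alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(x = "Time after bleach (s)", y = "Normalized intensity") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot_elptools
#' @export
autoplot.amide1_fit <- function(object, ...) {
  comps <- object$components
  wn <- object$fitted$wavenumber
  comp_df <- purrr::map_dfr(seq_len(nrow(comps)), function(j) {
    tibble(
      wavenumber = wn,
      absorbance = comps$amplitude[j] *
        exp(-(wn - comps$center[j])^2 / (2 * comps$width[j]^2)),
      component = sprintf("%.0f", comps$canonical_center[j])
    )
  })
  ggplot2::ggplot(object$fitted, ggplot2::aes(x = .data$wavenumber)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$absorbance), alpha = 0.3, size = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "black") +
    ggplot2::geom_line(
      data = comp_df,
      ggplot2::aes(y = .data$absorbance, colour = .data$component)
    ) +
    ggplot2::labs(x = "Wavenumber (1/cm)", y = "Absorbance (a.u.)",
                  colour = "Component") +
    ggplot2::theme_minimal()
}
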
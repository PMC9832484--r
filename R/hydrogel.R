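# Quantitative hydrogel characterization: rubber-elasticity mesh size,
# FRAP normalization and single-exponential recovery fitting,
# Stokes-Einstein and in-gel diffusivities, probe-based mesh bounds, and
# five-Gaussian amide-I band deconvolution.

#' Hydrogel mesh size from the storage modulus
#'
#' Rubber elasticity relates the plateau storage modulus of a flexible
#' network to the thermal energy per mesh volume, `G' = kB T / xi^3`, so
#' the typical distance between cross-links is
#' `xi = (kB T / G')^(1/3)`.
#'
#' @param gprime Storage modulus G' in Pa (vectorized).
#' @param temperature Absolute temperature in K (37 degrees C is 310.15 K;
#'   see [celsius_to_kelvin()]).
#' @return A tibble of class `mesh_estimate` with columns `gprime`,
#'   `temperature`, `xi_m` (m) and `xi_nm` (nm).
#' @export
#' @examples
#' mesh_size_from_modulus(47440, celsius_to_kelvin(37))
mesh_size_from_modulus <- function(gprime, temperature = 310.15) {
  if (any(gprime <= 0)) abort("Storage modulus must be positive")
  if (any(temperature <= 0)) abort("Temperature must be positive (Kelvin)")
  xi <- (.kB * temperature / gprime)^(1 / 3)
  out <- tibble(gprime = gprime, temperature = temperature,
                xi_m = xi, xi_nm = xi * 1e9)
  class(out) <- c("mesh_estimate", class(out))
  out
}

#' Free diffusivity from the Stokes-Einstein relation
#'
#' `D0 = kB T / (6 pi eta r)` for a sphere of hydrodynamic radius `r` in a
#' solvent of viscosity `eta`.
#'
#' @param radius Particle hydrodynamic radius in m (vectorized).
#' @param viscosity Solvent viscosity in Pa s (water at 37 degrees C:
#'   0.692e-3).
#' @param temperature Absolute temperature in K.
#' @return Diffusivity in um^2/s.
#' @export
#' @examples
#' stokes_einstein_d0(4.5e-9)
stokes_einstein_d0 <- function(radius, viscosity = 0.692e-3,
                               temperature = 310.15) {
  if (any(radius <= 0) || any(viscosity <= 0) || any(temperature <= 0)) {
    abort("radius, viscosity and temperature must all be positive")
  }
  d0_m2 <- .kB * temperature / (6 * pi * viscosity * radius)
  d0_m2 * 1e12
}

#' In-gel diffusivity from FRAP recovery rates
#'
#' With a fixed bleach geometry the diffusivity scales as
#' `D ~ k_FRAP L^2`, so the in-gel diffusivity follows from the free one
#' by the ratio of recovery rates: `D_gel = D0 k_gel / k_solution`.
#'
#' @param k_gel Recovery rate in the hydrogel, 1/s.
#' @param k_solution Recovery rate in pure solution, 1/s.
#' @param d0 Free (solution) diffusivity, um^2/s.
#' @return A tibble with columns `d_hydrogel` (um^2/s) and `ratio`
#'   (`d_hydrogel / d0`).
#' @export
#' @examples
#' gel_diffusivity(0.115, 0.179, 73.0)
gel_diffusivity <- function(k_gel, k_solution, d0) {
  if (any(k_gel <= 0) || any(k_solution <= 0) || any(d0 <= 0)) {
    abort("Rates and diffusivity must be positive")
  }
  d <- d0 * k_gel / k_solution
  tibble(d_hydrogel = d, ratio = d / d0)
}

#' Probe-based upper bound on the mesh size
#'
#' A probe whose diffusion is hindered must be comparable to or larger
#' than the mesh, so the mesh size is bounded above by the diameter of the
#' smallest hindered probe.
#'
#' @param probe_radii Probe hydrodynamic radii (any consistent length
#'   unit).
#' @param hindered Logical vector: was each probe's diffusion hindered?
#' @return `2 * min(probe_radii[hindered])` in the input unit, or `NULL`
#'   when no probe was hindered.
#' @export
#' @examples
#' probe_mesh_bound(8.5, TRUE) # nm in, nm out
probe_mesh_bound <- function(probe_radii, hindered) {
  stopifnot(length(probe_radii) == length(hindered))
  if (!any(hindered)) return(NULL)
  2 * min(probe_radii[hindered])
}

#' Full-scale normalization of a FRAP trace
#'
#' Divides the bleach-ROI intensity by the whole-field intensity (which
#' corrects for laser fluctuations, acquisition photobleaching and
#' fluorescence loss), then rescales so that the pre-bleach mean is 1 and
#' the first post-bleach point is 0.
#'
#' @param roi Bleach-ROI intensity series.
#' @param whole_field Whole-imaging-area intensity series (same length).
#' @param times Acquisition times in s (same length).
#' @param n_baseline Number of pre-bleach frames (default 10).
#' @return A tibble of class `frap_trace` with columns `time` (original),
#'   `time_post` (0 at the first post-bleach frame, `NA` before),
#'   `intensity` (normalized) and `phase` (`"pre"`/`"post"`).
#' @export
normalize_frap <- function(roi, whole_field, times, n_baseline = 10) {
  n <- length(roi)
  stopifnot(length(whole_field) == n, length(times) == n)
  if (n_baseline < 1 || n_baseline >= n) {
    abort("`n_baseline` must leave at least one post-bleach frame")
  }
  if (any(whole_field <= 0)) abort("Whole-field intensity must be positive")
  corrected <- roi / whole_field
  pre <- mean(corrected[seq_len(n_baseline)])
  post0 <- corrected[n_baseline + 1]
  if (abs(pre - post0) < .Machine$double.eps^0.5) {
    abort("No bleach detected: pre-bleach and first post-bleach levels coincide")
  }
  intensity <- (corrected - post0) / (pre - post0)
  phase <- rep(c("pre", "post"), c(n_baseline, n - n_baseline))
  t0 <- times[n_baseline + 1]
  out <- tibble(
    time = times,
    time_post = ifelse(phase == "post", times - t0, NA_real_),
    intensity = intensity,
    phase = phase
  )
  class(out) <- c("frap_trace", class(out))
  out
}

#' Fit a single-exponential FRAP recovery
#'
#' Least-squares (Levenberg-Marquardt) fit of
#' `I(t) = A (1 - exp(-k_FRAP t))` to the post-bleach portion of a
#' normalized trace, where `A` is the mobile plateau and `k_FRAP` the
#' recovery rate.
#'
#' @param trace A `frap_trace` from [normalize_frap()] or
#'   [gen_frap_trace()], or any tibble with `time` and `intensity`
#'   columns (all points treated as post-bleach, time zeroed at the first
#'   point).
#' @return A list of class `frap_fit`: `A`, `k_frap`, standard errors
#'   `A_se`/`k_se`, `converged`, `fitted` tibble, `residual_sd`.
#' @export
fit_frap <- function(trace) {
  if ("phase" %in% names(trace)) {
    post <- trace[trace$phase == "post", ]
    tt <- post$time_post
    ii <- post$intensity
  } else {
    tt <- trace$time - trace$time[1]
    ii <- trace$intensity
  }
  if (length(tt) < 10) abort("Need at least 10 post-bleach points")
  plateau0 <- mean(ii[tt >= stats::quantile(tt, 0.8)])
  if (!is.finite(plateau0) || plateau0 <= 0 || max(abs(ii)) < 1e-12) {
    fit <- NULL
  } else {
    half_idx <- which(ii >= plateau0 / 2)
    k0 <- if (length(half_idx) > 0 && tt[half_idx[1]] > 0) {
      log(2) / tt[half_idx[1]]
    } else {
      1 / max(tt)
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(
        ii ~ A * (1 - exp(-k * tt)),
        start = list(A = plateau0, k = k0),
        lower = c(A = 0, k = 1e-12),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
  }
  if (is.null(fit)) {
    warn("FRAP fit did not converge; estimates are NA")
    return(structure(
      list(A = NA_real_, k_frap = NA_real_, A_se = NA_real_, k_se = NA_real_,
           converged = FALSE,
           fitted = tibble(time = tt, intensity = ii, fitted = NA_real_),
           residual_sd = NA_real_),
      class = "frap_fit"
    ))
  }
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(A = NA_real_, k = NA_real_))
  structure(
    list(
      A = unname(est["A"]), k_frap = unname(est["k"]),
      A_se = unname(se["A"]), k_se = unname(se["k"]),
      converged = TRUE,
      fitted = tibble(time = tt, intensity = ii,
                      fitted = as.numeric(predict(fit))),
      residual_sd = sd(ii - as.numeric(predict(fit)))
    ),
    class = "frap_fit"
  )
}

#' @export
print.frap_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<frap_fit> A = %.4f (se %.2g), k_FRAP = %.4f 1/s (se %.2g)\n",
                x$A, x$A_se, x$k_frap, x$k_se))
  } else {
    cat("<frap_fit> not converged\n")
  }
  invisible(x)
}

# canonical amide-I component centres (1/cm) and assignments
.amide1_centers <- c(1620, 1645, 1660, 1670, 1700)
.amide1_assign <- c("beta_sheet", "random_coil_helix", "random_coil_helix",
                    "random_coil_helix", "beta_turn")
.amide1_window <- c(1595, 1705)

#' Normalize the amide-I region of an infrared spectrum
#'
#' Scales the whole spectrum so the maximum absorbance inside the amide-I
#' window equals 1.
#'
#' @param spectrum Tibble with columns `wavenumber` (1/cm, ascending) and
#'   `absorbance`.
#' @param window Amide-I window, 1/cm (default 1595-1705).
#' @return The normalized spectrum tibble.
#' @export
normalize_amide1 <- function(spectrum, window = .amide1_window) {
  wn <- spectrum$wavenumber
  if (is.unsorted(wn)) abort("Wavenumbers must be ascending")
  in_win <- wn >= window[1] & wn <= window[2]
  if (!any(in_win)) abort("Spectrum does not cover the amide-I window")
  peak <- max(spectrum$absorbance[in_win])
  if (peak <= 0) abort("Maximum absorbance in the amide-I window is not positive")
  spectrum$absorbance <- spectrum$absorbance / peak
  spectrum
}

#' Deconvolve the amide-I band into five Gaussian components
#'
#' Levenberg-Marquardt least-squares fit of five Gaussians over the
#' amide-I window, with centres box-constrained to +/- `shift` of the
#' canonical positions 1620 (beta-sheet), 1645/1660/1670 (random
#' coil/helix) and 1700 (beta-turn) 1/cm. Component areas follow
#' analytically (`amplitude * width * sqrt(2 pi)`); the ordered-structure
#' fraction pools the beta-sheet and beta-turn areas.
#'
#' @param spectrum A normalized spectrum (see [normalize_amide1()]).
#' @param centers Canonical component centres, 1/cm.
#' @param shift Allowed centre shift, 1/cm (default 4).
#' @param window Amide-I window, 1/cm.
#' @return A list of class `amide1_fit`: `components` tibble (center,
#'   amplitude, width, area, area_fraction, assignment), `ordered_fraction`,
#'   `converged`, `residual_sd`, `fitted` tibble.
#' @export
deconvolve_amide1 <- function(spectrum, centers = .amide1_centers,
                              shift = 4, window = .amide1_window) {
  in_win <- spectrum$wavenumber >= window[1] & spectrum$wavenumber <= window[2]
  wn <- spectrum$wavenumber[in_win]
  ab <- spectrum$absorbance[in_win]
  if (length(wn) < 3 * length(centers)) {
    abort("Too few points in the amide-I window for a stable fit")
  }
  k <- length(centers)
  width0 <- diff(window) / 20
  amp0 <- pmax(vapply(centers, function(c0) ab[which.min(abs(wn - c0))],
                      numeric(1)), 1e-3)
  par_names <- c(paste0("a", seq_len(k)), paste0("m", seq_len(k)),
                 paste0("s", seq_len(k)))
  gauss_sum <- function(par) {
    a <- par[seq_len(k)]
    m <- par[k + seq_len(k)]
    s <- par[2 * k + seq_len(k)]
    rowSums(vapply(seq_len(k), function(j) {
      a[j] * exp(-(wn - m[j])^2 / (2 * s[j]^2))
    }, numeric(length(wn))))
  }
  res_fn <- function(par) ab - gauss_sum(par)
  start <- c(amp0, centers, rep(width0, k))
  lower <- c(rep(0, k), centers - shift, rep(0.5, k))
  upper <- c(rep(Inf, k), centers + shift, rep(diff(window), k))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper, fn = res_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL
  )
  converged <- !is.null(fit) && fit$info %in% 1:4
  if (is.null(fit)) {
    warn("Amide-I deconvolution failed")
    return(structure(
      list(components = NULL, ordered_fraction = NA_real_, converged = FALSE,
           residual_sd = NA_real_, fitted = NULL),
      class = "amide1_fit"
    ))
  }
  if (!converged) warn("Amide-I deconvolution did not report convergence")
  par <- fit$par
  a <- par[seq_len(k)]
  m <- par[k + seq_len(k)]
  s <- par[2 * k + seq_len(k)]
  area <- a * s * sqrt(2 * pi)
  comps <- tibble(
    canonical_center = centers,
    center = m, amplitude = a, width = s, area = area,
    area_fraction = area / sum(area),
    assignment = .amide1_assign[seq_len(k)]
  )
  ordered <- sum(comps$area_fraction[comps$assignment %in%
                                       c("beta_sheet", "beta_turn")])
  structure(
    list(
      components = comps,
      ordered_fraction = ordered,
      converged = converged,
      residual_sd = sd(res_fn(par)),
      fitted = tibble(wavenumber = wn, absorbance = ab,
                      fitted = gauss_sum(par))
    ),
    class = "amide1_fit"
  )
}

#' @export
print.amide1_fit <- function(x, ...) {
  if (is.null(x$components)) {
    cat("<amide1_fit> failed\n")
    return(invisible(x))
  }
  cat(sprintf("<amide1_fit> ordered fraction %.3f; residual sd %.2g\n",
              x$ordered_fraction, x$residual_sd))
  print(x$components)
  invisible(x)
}
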
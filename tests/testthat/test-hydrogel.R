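# Mesh size, diffusivities, FRAP normalization/fitting and amide-I
# deconvolution.

test_that("mesh size obeys the rubber-elasticity relation exactly", {
  m <- mesh_size_from_modulus(c(47440, 20000, 38690), 310.15)
  expect_equal(round(m$xi_nm, 1), c(4.5, 6.0, 4.8))
  # xi^3 G' = kB T
  expect_equal(m$xi_m^3 * m$gprime, rep(1.380649e-23 * 310.15, 3),
               tolerance = 1e-9)
  # doubling G' shrinks xi by 2^(1/3)
  expect_equal(mesh_size_from_modulus(2000)$xi_nm /
                 mesh_size_from_modulus(4000)$xi_nm,
               2^(1 / 3), tolerance = 1e-12)
  expect_error(mesh_size_from_modulus(-1), "positive")
})

test_that("Stokes-Einstein diffusivities reproduce the dextran values", {
  expect_equal(round(stokes_einstein_d0(4.5e-9), 1), 73.0)
  expect_equal(round(stokes_einstein_d0(8.5e-9), 1), 38.6)
  # inverse relation: D0 * 6 pi eta r = kB T
  r <- 3.3e-9
  d0 <- stokes_einstein_d0(r) * 1e-12
  expect_equal(d0 * 6 * pi * 0.692e-3 * r, 1.380649e-23 * 310.15,
               tolerance = 1e-12)
  expect_equal(stokes_einstein_d0(2e-9) / stokes_einstein_d0(4e-9), 2)
})

test_that("gel diffusivity is the rate-scaled free diffusivity", {
  expect_equal(gel_diffusivity(0.1, 0.1, 50)$d_hydrogel, 50)
  g <- gel_diffusivity(0.115, 0.179, 73.0)
  expect_equal(g$d_hydrogel, 73.0 * 0.115 / 0.179, tolerance = 1e-12)
  # printed-rate arithmetic lands near the published in-gel value
  expect_equal(g$d_hydrogel, 46.9, tolerance = 0.015)
  # scale-free in the rates
  expect_equal(gel_diffusivity(0.23, 0.358, 73.0)$d_hydrogel, g$d_hydrogel)
  expect_equal(gel_diffusivity(0.05, 0.1, 40)$d_hydrogel,
               2 * gel_diffusivity(0.025, 0.1, 40)$d_hydrogel)
})

test_that("probe bound is twice the smallest hindered radius", {
  expect_equal(probe_mesh_bound(8.5, TRUE), 17)
  expect_equal(probe_mesh_bound(c(4.5, 8.5), c(TRUE, TRUE)), 9)
  expect_null(probe_mesh_bound(c(4.5, 8.5), c(FALSE, FALSE)))
})

test_that("full-scale FRAP normalization pins pre/post levels", {
  n <- 60
  times <- seq(0, 59)
  roi <- c(rep(100, 10), rep(40, n - 10))
  field <- rep(200, n)
  tr <- normalize_frap(roi, field, times)
  expect_equal(tr$intensity[tr$phase == "pre"], rep(1, 10))
  expect_equal(tr$intensity[11], 0)
  expect_equal(tr$time_post[11], 0)

  # a shared linear decay cancels out
  decay <- seq(1, 0.9, length.out = n)
  tr2 <- normalize_frap(roi * decay, field * decay, times)
  expect_equal(tr2$intensity, tr$intensity, tolerance = 1e-12)

  expect_error(normalize_frap(roi, rep(0, n), times), "positive")
})

test_that("FRAP fitting inverts noiseless traces and flags degenerate ones", {
  tr <- gen_frap_trace(A = 0.8, k = 0.115, sigma = 0, seed = 1)
  fit <- fit_frap(tr)
  expect_true(fit$converged)
  expect_equal(fit$A, 0.8, tolerance = 1e-8)
  expect_equal(fit$k_frap, 0.115, tolerance = 1e-8)

  flat <- tibble::tibble(time = seq(0, 99), intensity = 0)
  expect_warning(bad <- fit_frap(flat), "converge")
  expect_false(bad$converged)

  expect_error(fit_frap(tibble::tibble(time = 1:5, intensity = 1:5)),
               "at least 10")
})

test_that("FRAP parameter recovery stays within 5% at study noise", {
  errs <- vapply(1:50, function(s) {
    tr <- gen_frap_trace(A = 0.8, k = 0.115, sigma = 0.01, n_points = 200,
                         t_max = 100, seed = 1000 + s)
    fit <- fit_frap(tr)
    c((fit$A - 0.8) / 0.8, (fit$k_frap - 0.115) / 0.115)
  }, numeric(2))
  expect_lt(max(abs(errs)), 0.05)
  # bias below 2%
  expect_lt(abs(mean(errs[1, ])), 0.02)
  expect_lt(abs(mean(errs[2, ])), 0.02)
})

test_that("amide-I normalization scales the window maximum to one", {
  sp <- gen_ftir_spectrum(amplitudes = c(2, 1, 3, 1, 0.5),
                          widths = rep(6, 5))
  ns <- normalize_amide1(sp)
  in_win <- ns$wavenumber >= 1595 & ns$wavenumber <= 1705
  expect_equal(max(ns$absorbance[in_win]), 1)
  expect_equal(normalize_amide1(ns)$absorbance, ns$absorbance)
  flat <- tibble::tibble(wavenumber = seq(650, 4000, 2), absorbance = 0)
  expect_error(normalize_amide1(flat), "positive")
})

test_that("amide-I deconvolution round-trips noiseless mixtures", {
  truth_amp <- c(0.9, 0.5, 0.8, 0.4, 0.3)
  truth_wid <- c(7, 9, 6, 8, 5)
  sp <- normalize_amide1(gen_ftir_spectrum(truth_amp, truth_wid))
  fit <- deconvolve_amide1(sp)
  expect_true(fit$converged)
  truth <- attr(gen_ftir_spectrum(truth_amp, truth_wid), "truth")
  expect_equal(fit$components$area_fraction, truth$area_fraction,
               tolerance = 1e-4)
  expect_equal(sum(fit$components$area_fraction), 1, tolerance = 1e-6)
  expect_true(all(abs(fit$components$center - fit$components$canonical_center)
                  <= 4 + 1e-9))
  # ordered fraction pools the 1620 and 1700 components
  expect_equal(fit$ordered_fraction,
               sum(truth$area_fraction[c(1, 5)]), tolerance = 1e-4)
})

test_that("a single beta-sheet band yields ordered fraction near one", {
  wn <- seq(650, 4000, 2)
  sp <- tibble::tibble(
    wavenumber = wn,
    absorbance = exp(-(wn - 1620)^2 / (2 * 6^2))
  )
  fit <- deconvolve_amide1(normalize_amide1(sp))
  expect_gt(fit$ordered_fraction, 0.98)
})

test_that("amide-I recovery of structure-class fractions at 1% noise", {
  # the three overlapping coil/helix components are not individually
  # identifiable under noise, so recovery is asserted on the pooled
  # assignment fractions (the quantities the analysis reports)
  truth_amp <- c(0.9, 0.5, 0.8, 0.4, 0.3)
  truth_wid <- c(7, 9, 6, 8, 5)
  truth <- attr(gen_ftir_spectrum(truth_amp, truth_wid), "truth")
  pool <- function(fr) c(fr[1], sum(fr[2:4]), fr[5])
  errs <- vapply(1:20, function(s) {
    sp <- gen_ftir_spectrum(truth_amp, truth_wid, sigma = 0.01,
                            seed = 500 + s)
    fit <- deconvolve_amide1(normalize_amide1(sp))
    c(
      max(abs(pool(fit$components$area_fraction) -
                pool(truth$area_fraction))),
      abs(fit$ordered_fraction -
            sum(truth$area_fraction[c(1, 5)]))
    )
  }, numeric(2))
  expect_lt(max(errs[1, ]), 0.05)
  expect_lt(max(errs[2, ]), 0.05)
  # bias of the ordered fraction below 2 points
  expect_lt(abs(mean(errs[2, ])), 0.02)
})
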
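# Seed-deterministic synthetic generators for every pipeline stage:
# two-cluster descriptor datasets, pseudo-peptide-in-water trajectories,
# noisy FRAP recoveries, and five-Gaussian amide-I spectra.

#' Specify a synthetic two-cluster descriptor dataset
#'
#' The generated dataset emulates the shape of an MD featurization study:
#' `2 * n_per_class` pseudo-ELPs, each with `n_replicas` replicas of
#' `n_timepoints` time points and `n_descriptors` descriptor columns. The
#' two classes differ by a mean shift of `delta` within-class standard
#' deviations on `n_informative` columns; time points within a replica
#' follow an AR(1) process with coefficient `rho` (MD frames are not
#' independent), scaled to unit marginal variance.
#'
#' @param n_per_class ELPs per class (default 4, i.e. 8 ELPs total).
#' @param n_replicas Replicas per ELP (default 3).
#' @param n_timepoints Time points per replica (default 250).
#' @param n_descriptors Descriptor columns (default 27).
#' @param n_informative Columns carrying the class shift (default 6).
#' @param delta Between-class mean shift in within-class sd units
#'   (default 4).
#' @param rho AR(1) coefficient in `[0, 1)` (default 0.5).
#' @param stride_ns Time spacing of the emulated sampling (default 0.2).
#' @param seed Mandatory RNG seed.
#' @return A list of class `cluster_spec`.
#' @export
cluster_spec <- function(n_per_class = 4, n_replicas = 3, n_timepoints = 250,
                         n_descriptors = 27, n_informative = 6, delta = 4,
                         rho = 0.5, stride_ns = 0.2, seed) {
  stopifnot(
    n_per_class >= 1, n_replicas >= 1, n_timepoints >= 2,
    n_informative <= n_descriptors, delta >= 0, rho >= 0, rho < 1
  )
  if (missing(seed)) abort("`seed` is required")
  structure(
    list(n_per_class = n_per_class, n_replicas = n_replicas,
         n_timepoints = n_timepoints, n_descriptors = n_descriptors,
         n_informative = n_informative, delta = delta, rho = rho,
         stride_ns = stride_ns, seed = as.integer(seed)),
    class = "cluster_spec"
  )
}

.ar1_series <- function(n, rho) {
  e <- rnorm(n)
  if (rho == 0) return(e)
  x <- numeric(n)
  x[1] <- e[1]
  scale_inn <- sqrt(1 - rho^2)
  for (t in 2:n) x[t] <- rho * x[t - 1] + scale_inn * e[t]
  x
}

#' Generate a two-cluster descriptor dataset
#'
#' @param spec A [cluster_spec()].
#' @return A list: `descriptors` (tibble: `elp`, `replica`, `time_ns`,
#'   descriptor columns), `labels` (tibble: `elp`, `label`), `truth`
#'   (list: `informative` column names, `delta`, `rho`).
#' @export
#' @examples
#' d <- gen_descriptor_dataset(cluster_spec(n_timepoints = 10, seed = 1))
#' dim(d$descriptors)
gen_descriptor_dataset <- function(spec) {
  stopifnot(inherits(spec, "cluster_spec"))
  withr::with_seed(spec$seed, {
    p <- spec$n_descriptors
    col_names <- if (p == 27) descriptor_registry()$name else sprintf("d%02d", seq_len(p))
    informative <- sort(sample.int(p, spec$n_informative))
    n_elps <- 2 * spec$n_per_class
    labels <- tibble(
      elp = sprintf("ELP%02d", seq_len(n_elps)),
      label = rep(c(0L, 1L), each = spec$n_per_class)
    )
    rows <- list()
    for (i in seq_len(n_elps)) {
      shift <- numeric(p)
      if (labels$label[i] == 1) shift[informative] <- spec$delta
      for (r in seq_len(spec$n_replicas)) {
        x <- vapply(seq_len(p), function(j) .ar1_series(spec$n_timepoints, spec$rho),
                    numeric(spec$n_timepoints))
        x <- sweep(x, 2, shift, "+")
        colnames(x) <- col_names
        rows[[length(rows) + 1]] <- dplyr::bind_cols(
          tibble(elp = labels$elp[i], replica = r,
                 time_ns = seq_len(spec$n_timepoints) * spec$stride_ns),
          as_tibble(x)
        )
      }
    }
    list(
      descriptors = bind_rows(rows),
      labels = labels,
      truth = list(informative = col_names[informative],
                   delta = spec$delta, rho = spec$rho)
    )
  })
}

#' Specify a synthetic polymer-in-water trajectory
#'
#' @param n_residues Chain length (default 40).
#' @param compactness `c` in `[0, 1]`: 0 generates an extended
#'   (persistent) chain, 1 a collapsed one (uncorrelated steps plus a
#'   centripetal bias).
#' @param n_waters Water molecules placed in the box (default 150).
#' @param box Cubic box edge, Angstrom (default 80).
#' @param n_frames Frames (default 25).
#' @param dt_ns Frame spacing, ns (default 0.2).
#' @param seed Mandatory RNG seed.
#' @return A list of class `chain_spec`.
#' @export
chain_spec <- function(n_residues = 40, compactness = 0.5, n_waters = 150,
                       box = 80, n_frames = 25, dt_ns = 0.2, seed) {
  stopifnot(
    n_residues >= 2, compactness >= 0, compactness <= 1,
    n_waters >= 0, box > 0, n_frames >= 1, dt_ns > 0
  )
  if (missing(seed)) abort("`seed` is required")
  # the chain must fit the box even when fully extended
  if (box < 3.8 * 2.5) abort("Box too small for the chain")
  structure(
    list(n_residues = n_residues, compactness = compactness,
         n_waters = n_waters, box = box, n_frames = n_frames,
         dt_ns = dt_ns, seed = as.integer(seed)),
    class = "chain_spec"
  )
}

# idealized nonbonded parameters for the pseudo-peptide and TIP3P-like
# water (charge e, eps kcal/mol, rmin/2 Angstrom, radius Angstrom)
.pseudo_params <- list(
  N  = c(q = -0.47, eps = 0.20,  rmin2 = 1.85,  radius = 1.55, mass = 14.007),
  HN = c(q = 0.31,  eps = 0.046, rmin2 = 0.225, radius = 1.20, mass = 1.008),
  CA = c(q = 0.07,  eps = 0.02,  rmin2 = 2.275, radius = 1.70, mass = 12.011),
  C  = c(q = 0.51,  eps = 0.11,  rmin2 = 2.00,  radius = 1.70, mass = 12.011),
  O  = c(q = -0.51, eps = 0.12,  rmin2 = 1.70,  radius = 1.52, mass = 15.999),
  CB = c(q = 0.09,  eps = 0.078, rmin2 = 2.05,  radius = 1.70, mass = 12.011),
  OW = c(q = -0.834, eps = 0.1521, rmin2 = 1.7682, radius = 1.52, mass = 15.999),
  HW = c(q = 0.417, eps = 0.046, rmin2 = 0.2245, radius = 1.20, mass = 1.008)
)

# one CA random walk with direction persistence (1 - c) and centripetal
# bias c; returns n x 3 matrix with 3.8 Angstrom steps
.gen_ca_walk <- function(n, compactness) {
  step <- 3.8
  clash <- 4.0 # excluded-volume diameter between non-bonded CA beads
  pos <- matrix(0, n, 3)
  dir <- c(1, 0, 0)
  for (i in 2:n) {
    centroid <- colMeans(pos[seq_len(i - 1), , drop = FALSE])
    pull <- centroid - pos[i - 1, ]
    np <- sqrt(sum(pull^2))
    pull <- if (np > 1e-9) pull / np else c(0, 0, 0)
    best_d <- NULL
    best_sep <- -Inf
    for (try in 1:50) {
      noise <- rnorm(3)
      noise <- noise / sqrt(sum(noise^2))
      d <- (1 - compactness) * dir + 0.8 * noise + 0.6 * compactness * pull
      d <- d / sqrt(sum(d^2))
      cand <- pos[i - 1, ] + step * d
      if (i <= 2) {
        best_d <- d
        break
      }
      dmin <- min(sqrt(colSums((t(pos[seq_len(i - 2), , drop = FALSE]) - cand)^2)))
      if (dmin > best_sep) {
        best_sep <- dmin
        best_d <- d
      }
      if (dmin >= clash) break
    }
    pos[i, ] <- pos[i - 1, ] + step * best_d
    dir <- d
  }
  pos
}

# decorate CA positions with N, C, O, CB pseudo-atoms in a local frame
.decorate_chain <- function(ca) {
  n <- nrow(ca)
  rows <- list()
  xyz <- list()
  # alternate hydrophobic/hydrophilic residues so SASA partitions are
  # non-trivial
  resnames <- rep(c("VAL", "SER"), length.out = n)
  for (i in seq_len(n)) {
    t_vec <- if (i < n) ca[i + 1, ] - ca[i, ] else ca[i, ] - ca[i - 1, ]
    t_vec <- t_vec / sqrt(sum(t_vec^2))
    ref <- if (abs(t_vec[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- ref - sum(ref * t_vec) * t_vec
    u <- u / sqrt(sum(u^2))
    v <- c(t_vec[2] * u[3] - t_vec[3] * u[2],
           t_vec[3] * u[1] - t_vec[1] * u[3],
           t_vec[1] * u[2] - t_vec[2] * u[1])
    add <- function(atom, element, offset, backbone) {
      rows[[length(rows) + 1]] <<- tibble(
        atom = atom, element = element, resid = i, resname = resnames[i],
        segment = "protein", is_backbone = backbone
      )
      xyz[[length(xyz) + 1]] <<- ca[i, ] + offset
    }
    add("N", "N", -1.46 * t_vec + 0.4 * u, TRUE)
    add("HN", "H", -1.46 * t_vec + 1.4 * u, FALSE)
    add("CA", "C", c(0, 0, 0), TRUE)
    add("C", "C", 1.52 * t_vec - 0.3 * u, TRUE)
    add("O", "O", 1.52 * t_vec - 1.5 * u, TRUE)
    add("CB", "C", 1.5 * v, FALSE)
  }
  list(atoms = bind_rows(rows), xyz = do.call(rbind, xyz))
}

#' Generate a pseudo-peptide-in-water trajectory
#'
#' Builds a backbone-plus-side-chain-bead chain per frame as a correlated
#' random walk whose persistence scales with `1 - compactness` (plus a
#' centripetal bias for collapsed chains), places waters uniformly in the
#' periodic box with a 2.5 Angstrom excluded-volume rejection, and
#' attaches idealized nonbonded parameters, so the result satisfies every
#' precondition of the descriptor calculations. Collapsed chains
#' (`compactness` near 1) have a smaller radius of gyration than extended
#' ones (`compactness` near 0).
#'
#' @param spec A [chain_spec()].
#' @param elp,replica Identifiers carried into descriptor tables.
#' @return An `elp_trajectory` (periodic, cubic box).
#' @export
gen_chain_trajectory <- function(spec, elp = "synthetic", replica = 1L) {
  stopifnot(inherits(spec, "chain_spec"))
  withr::with_seed(spec$seed, {
    n_res <- spec$n_residues
    first <- .decorate_chain(.gen_ca_walk(n_res, spec$compactness))
    atoms <- first$atoms
    if (spec$n_waters > 0) {
      wrows <- purrr::map_dfr(seq_len(spec$n_waters), function(w) {
        tibble(
          atom = c("OW", "HW1", "HW2"), element = c("O", "H", "H"),
          resid = n_res + w, resname = "HOH", segment = "water",
          is_backbone = FALSE
        )
      })
      atoms <- bind_rows(atoms, wrows)
    }
    # parameters and flags
    key <- ifelse(atoms$segment == "water",
                  ifelse(atoms$element == "O", "OW", "HW"), atoms$atom)
    par <- do.call(rbind, .pseudo_params[key])
    atoms$charge <- par[, "q"]
    atoms$eps <- par[, "eps"]
    atoms$rmin2 <- par[, "rmin2"]
    atoms$radius <- par[, "radius"]
    atoms$mass <- par[, "mass"]
    atoms$is_acceptor <- atoms$element == "O" |
      (atoms$segment == "protein" & atoms$atom == "N")
    atoms$is_polar_h <- atoms$element == "H"
    atoms$h_parent <- NA_integer_
    for (i in which(atoms$is_polar_h)) {
      parent_name <- if (atoms$segment[i] == "water") "OW" else "N"
      atoms$h_parent[i] <- which(atoms$resid == atoms$resid[i] &
                                   atoms$atom == parent_name)[1]
    }
    atoms$is_donor <- seq_len(nrow(atoms)) %in% atoms$h_parent
    top <- new_topology(atoms)

    n_atoms <- nrow(atoms)
    coords <- array(NA_real_, dim = c(spec$n_frames, n_atoms, 3))
    half <- spec$box / 2
    for (f in seq_len(spec$n_frames)) {
      chain <- if (f == 1) first else .decorate_chain(.gen_ca_walk(n_res, spec$compactness))
      pxyz <- chain$xyz
      # centre the chain in the box
      pxyz <- sweep(pxyz, 2, colMeans(pxyz))
      frame_xyz <- pxyz
      if (spec$n_waters > 0) {
        placed <- 0
        wxyz <- matrix(NA_real_, spec$n_waters * 3, 3)
        while (placed < spec$n_waters) {
          o <- runif(3, -half, half)
          dmin <- min(sqrt(colSums((t(pxyz) - o)^2)))
          if (dmin < 2.5) next
          h1 <- o + c(0.9572, 0, 0)
          ang <- 104.52 * pi / 180
          h2 <- o + 0.9572 * c(cos(ang), sin(ang), 0)
          wxyz[placed * 3 + 1:3, ] <- rbind(o, h1, h2)
          placed <- placed + 1
        }
        frame_xyz <- rbind(pxyz, wxyz)
      }
      coords[f, , ] <- frame_xyz
    }
    new_trajectory(top, coords, times = seq_len(spec$n_frames) * spec$dt_ns,
                   box = rep(spec$box, 3), elp = elp, replica = replica)
  })
}

#' Generate a noisy single-exponential FRAP recovery
#'
#' `I(t) = A (1 - exp(-k t)) + N(0, sigma^2)` on a uniform post-bleach
#' time grid.
#'
#' @param A Mobile plateau (default 0.8).
#' @param k Recovery rate, 1/s (default 0.115).
#' @param sigma Gaussian noise sd (default 0.01).
#' @param n_points Number of points (default 200).
#' @param t_max Trace duration, s (default 100).
#' @param seed Mandatory RNG seed.
#' @return A `frap_trace` tibble (`time`, `time_post`, `intensity`,
#'   `phase = "post"`), with attribute `truth = c(A, k)`.
#' @export
gen_frap_trace <- function(A = 0.8, k = 0.115, sigma = 0.01, n_points = 200,
                           t_max = 100, seed) {
  stopifnot(A > 0, k > 0, t_max > 0, sigma >= 0, n_points >= 2)
  if (missing(seed)) abort("`seed` is required")
  withr::with_seed(seed, {
    tt <- seq(0, t_max, length.out = n_points)
    ii <- A * (1 - exp(-k * tt)) + rnorm(n_points, sd = sigma)
    out <- tibble(time = tt, time_post = tt, intensity = ii, phase = "post")
    attr(out, "truth") <- c(A = A, k = k)
    class(out) <- c("frap_trace", class(out))
    out
  })
}

#' Generate a synthetic infrared spectrum with an amide-I band
#'
#' Sum of five Gaussians at the canonical amide-I component positions on a
#' 650-4000 1/cm grid at 2 1/cm spacing, plus optional Gaussian noise.
#'
#' @param amplitudes Five positive component amplitudes.
#' @param widths Five positive component widths (Gaussian sd, 1/cm).
#' @param centers Component centres (default the canonical five).
#' @param sigma Noise sd (default 0).
#' @param range Wavenumber range, 1/cm (default 650-4000).
#' @param resolution Grid spacing, 1/cm (default 2).
#' @param seed RNG seed (required when `sigma > 0`).
#' @return A tibble (`wavenumber`, `absorbance`) with attribute `truth`
#'   (tibble of the generating components and their area fractions).
#' @export
gen_ftir_spectrum <- function(amplitudes, widths,
                              centers = c(1620, 1645, 1660, 1670, 1700),
                              sigma = 0, range = c(650, 4000),
                              resolution = 2, seed = NULL) {
  k <- length(centers)
  stopifnot(length(amplitudes) == k, length(widths) == k,
            all(amplitudes > 0), all(widths > 0))
  if (sigma > 0 && is.null(seed)) abort("`seed` is required when sigma > 0")
  wn <- seq(range[1], range[2], by = resolution)
  ab <- rowSums(vapply(seq_len(k), function(j) {
    amplitudes[j] * exp(-(wn - centers[j])^2 / (2 * widths[j]^2))
  }, numeric(length(wn))))
  if (sigma > 0) {
    ab <- withr::with_seed(seed, ab + rnorm(length(wn), sd = sigma))
  }
  area <- amplitudes * widths * sqrt(2 * pi)
  out <- tibble(wavenumber = wn, absorbance = ab)
  attr(out, "truth") <- tibble(
    center = centers, amplitude = amplitudes, width = widths,
    area_fraction = area / sum(area)
  )
  out
}
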
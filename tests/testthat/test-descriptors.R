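# Geometry and energy descriptors against closed forms and brute-force
# double-loop oracles.

test_that("radius of gyration matches trivial cases and the oracle", {
  expect_equal(radius_of_gyration(matrix(c(3, -2, 7), 1)), 0)
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0))), 1)

  set.seed(7)
  xyz <- matrix(rnorm(30, sd = 4), 10)
  mass <- runif(10, 1, 16)
  expect_equal(radius_of_gyration(xyz, mass = mass),
               oracle_rg(xyz, mass), tolerance = 1e-10)
})

test_that("Rg and RMSD are invariant to rigid-body motion", {
  set.seed(11)
  xyz <- matrix(rnorm(45), 15)
  for (i in 1:5) {
    th <- runif(3, 0, 2 * pi)
    rx <- matrix(c(1, 0, 0, 0, cos(th[1]), -sin(th[1]),
                   0, sin(th[1]), cos(th[1])), 3, 3, byrow = TRUE)
    rz <- matrix(c(cos(th[2]), -sin(th[2]), 0, sin(th[2]), cos(th[2]), 0,
                   0, 0, 1), 3, 3, byrow = TRUE)
    moved <- xyz %*% t(rx %*% rz) + matrix(rnorm(3, sd = 10), 15, 3,
                                           byrow = TRUE)
    expect_lt(abs(radius_of_gyration(moved) - radius_of_gyration(xyz)), 1e-8)
    expect_lt(rmsd_superposed(moved, xyz), 1e-8)
  }
})

test_that("superposed RMSD matches a numeric optimization oracle", {
  set.seed(3)
  ref <- matrix(rnorm(12), 4)
  frame <- ref + matrix(rnorm(12, sd = 0.3), 4)
  # oracle: minimize RMSD over rotations parameterized by Euler angles
  obj <- function(par) {
    cx <- cos(par[1]); sx <- sin(par[1])
    cy <- cos(par[2]); sy <- sin(par[2])
    cz <- cos(par[3]); sz <- sin(par[3])
    rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
    ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
    rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    a <- sweep(frame, 2, colMeans(frame)) %*% t(rx %*% ry %*% rz)
    b <- sweep(ref, 2, colMeans(ref))
    sqrt(sum((a - b)^2) / nrow(ref))
  }
  best <- Inf
  for (start in list(c(0, 0, 0), c(1, 1, 1), c(-1, 2, 0.5), c(2, -2, 1))) {
    o <- optim(start, obj, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))
    best <- min(best, o$value)
  }
  expect_equal(as.numeric(rmsd_superposed(frame, ref)), best,
               tolerance = 1e-6)
})

test_that("degenerate references fall back to translation-only with a flag", {
  line <- cbind(0:3, 0, 0)
  frame <- line + matrix(c(0, 0.1, 0), 4, 3, byrow = TRUE)
  expect_warning(out <- rmsd_superposed(frame, line), "egenerate")
  expect_true(attr(out, "degenerate"))
})

test_that("hydrogen-bond counting honours constructed geometries", {
  top <- new_topology(tibble::tibble(
    atom = c("N", "HN", "O"), element = c("N", "H", "O"),
    resid = c(1, 1, 2), resname = "GLY", segment = "protein",
    is_acceptor = c(FALSE, FALSE, TRUE), is_polar_h = c(FALSE, TRUE, FALSE),
    h_parent = c(NA, 1L, NA), is_donor = c(TRUE, FALSE, FALSE)
  ))
  linear <- rbind(c(0, 0, 0), c(0.96, 0, 0), c(2.80, 0, 0))
  expect_equal(as.integer(count_hbonds(linear, top, 1, 3)), 1L)

  far <- linear
  far[3, ] <- c(4.0, 0, 0)
  expect_equal(as.integer(count_hbonds(far, top, 1, 3)), 0L)

  # bent past the 30 degree deviation: rotate the acceptor about H
  bent <- linear
  bent[3, ] <- c(0.96, 0, 0) + 1.84 * c(cos(140 * pi / 180),
                                        sin(140 * pi / 180), 0)
  expect_equal(as.integer(count_hbonds(bent, top, 1, 3)), 0L)
})

test_that("pairwise descriptors equal brute-force oracles on random systems", {
  for (seed in c(2, 9)) {
    sys <- make_mixed_system(n_protein = 12, n_waters = 14, seed = seed,
                             spread = 8)
    donors <- which(sys$top$is_donor)
    acceptors <- which(sys$top$is_acceptor)
    for (box in list(NULL, c(17, 17, 17))) {
      got <- suppressWarnings(
        count_hbonds(sys$xyz, sys$top, donors, acceptors, box = box)
      )
      expect_identical(as.integer(got),
                       oracle_hbonds(sys$xyz, sys$top, donors, acceptors,
                                     box = box))
      got_shell <- suppressWarnings(
        hydration_shell_waters(sys$xyz, sys$top, box = box)
      )
      expect_identical(as.integer(got_shell),
                       oracle_shell(sys$xyz, sys$top, box = box))
      prot <- which(sys$top$segment == "protein")
      wat <- which(sys$top$segment == "water")
      en <- nonbonded_energy(sys$xyz, sys$top, prot, wat, box = box)
      or <- oracle_energy(sys$xyz, sys$top, prot, wat, box = box)
      expect_equal(en$electrostatic, or$elec, tolerance = 1e-8)
      expect_equal(en$vdw, or$vdw, tolerance = 1e-8)
      en_i <- nonbonded_energy(sys$xyz, sys$top, prot, prot, box = box)
      or_i <- oracle_energy(sys$xyz, sys$top, prot, prot, box = box)
      expect_equal(en_i$electrostatic, or_i$elec, tolerance = 1e-8)
      expect_equal(en_i$vdw, or_i$vdw, tolerance = 1e-8)
    }
  }
})

test_that("nonbonded closed forms hold", {
  # residues 1 and 3: outside the same/adjacent-residue exclusion
  top <- new_topology(tibble::tibble(
    atom = c("X", "Y"), element = "C", resid = c(1L, 3L), resname = "UNK",
    segment = "protein", charge = c(1, 1), eps = c(0.25, 0.25),
    rmin2 = c(1.5, 1.5)
  ))
  # two +1e charges at 5 A, inside the switch distance
  e <- nonbonded_energy(rbind(c(0, 0, 0), c(5, 0, 0)), top, 1:2, 1:2)
  expect_equal(e$electrostatic, 332.0636 / 5, tolerance = 1e-10)
  # LJ minimum at combined rmin: well depth -eps
  e2 <- nonbonded_energy(rbind(c(0, 0, 0), c(3, 0, 0)), top, 1:2, 1:2)
  expect_equal(e2$vdw, -0.25, tolerance = 1e-10)
  # beyond the cutoff: zero
  e3 <- nonbonded_energy(rbind(c(0, 0, 0), c(13, 0, 0)), top, 1:2, 1:2)
  expect_equal(e3$electrostatic + e3$vdw, 0)
})

test_that("SASA matches the closed form and converges", {
  # isolated atom: 4 pi (r + probe)^2
  one <- sasa_atoms(matrix(0, 1, 3), 1.9, n_points = 960)
  expect_equal(one, 4 * pi * 3.3^2, tolerance = 1e-3)

  # two coincident identical atoms occlude to a single atom's area
  two <- sasa_atoms(matrix(0, 2, 3, byrow = TRUE), c(1.9, 1.9),
                    n_points = 480)
  expect_equal(sum(two), 4 * pi * 3.3^2, tolerance = 1e-3)

  # separating atoms: total non-decreasing up to twice the isolated area
  radii <- c(1.7, 1.7)
  seps <- seq(0, 7, by = 0.5)
  totals <- vapply(seps, function(s) {
    sum(sasa_atoms(rbind(c(0, 0, 0), c(s, 0, 0)), radii, n_points = 480))
  }, numeric(1))
  expect_true(all(diff(totals) > -1e-6))
  expect_equal(totals[length(totals)], 2 * 4 * pi * 3.1^2, tolerance = 1e-3)

  # convergence: doubling the point count changes a 20-atom total < 1%
  set.seed(5)
  xyz <- matrix(rnorm(60, sd = 3), 20)
  r <- runif(20, 1.2, 1.9)
  a1 <- sum(sasa_atoms(xyz, r, n_points = 240))
  a2 <- sum(sasa_atoms(xyz, r, n_points = 480))
  expect_lt(abs(a2 - a1) / a2, 0.01)
})

test_that("SASA partition is exact and missing radii are rejected", {
  sys <- make_mixed_system(n_protein = 8, n_waters = 2, seed = 3)
  s <- sasa(sys$xyz, sys$top, n_points = 120)
  expect_equal(s$hydrophobic + s$hydrophilic, s$total, tolerance = 1e-9)
  expect_equal(s$backbone + s$sidechain, s$total, tolerance = 1e-9)
  expect_error(sasa_atoms(matrix(0, 1, 3), NA_real_), "radius")
})

test_that("hydration shell counts each water once", {
  atoms <- tibble::tibble(
    atom = c("CA", "OW", "HW1", "HW2"), element = c("C", "O", "H", "H"),
    resid = c(1, 2, 2, 2), resname = c("GLY", "HOH", "HOH", "HOH"),
    segment = c("protein", "water", "water", "water"),
    is_backbone = c(TRUE, FALSE, FALSE, FALSE)
  )
  top <- new_topology(atoms)
  near <- rbind(c(0, 0, 0), c(3.0, 0, 0), c(3.96, 0, 0), c(2.76, 0.93, 0))
  expect_equal(as.integer(hydration_shell_waters(near, top)), 1L)
  far <- near
  far[2:4, 1] <- far[2:4, 1] + 0.3
  expect_equal(as.integer(hydration_shell_waters(far, top)), 0L)
})

test_that("descriptor tables are deterministic and correctly shaped", {
  traj <- gen_chain_trajectory(chain_spec(n_residues = 8, n_waters = 10,
                                          n_frames = 4, seed = 21))
  d1 <- sample_descriptors(traj, start_ns = 0.2, stride_ns = 0.2,
                           sasa_points = 60)
  d2 <- sample_descriptors(traj, start_ns = 0.2, stride_ns = 0.2,
                           sasa_points = 60)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 3)
  expect_equal(ncol(d1), 3 + 27)
  expect_named(d1, c("elp", "replica", "time_ns", descriptor_registry()$name))
  # fractions sum to one; counts non-negative
  ss_sum <- d1$helix_frac + d1$sheet_frac + d1$turn_frac + d1$coil_frac
  expect_equal(ss_sum, rep(1, 3), tolerance = 1e-12)
  expect_true(all(d1$hbonds_intra >= 0 & d1$hydration_waters >= 0))
  # first sampled frame is its own RMSD reference
  expect_equal(d1$rmsd_backbone[1], 0)
})

test_that("sampling window arithmetic matches the study design", {
  top <- new_topology(tibble::tibble(
    atom = c("N", "CA", "C"), element = c("N", "C", "C"), resid = 1,
    resname = "GLY", segment = "protein",
    is_backbone = TRUE
  ))
  n_frames <- 750
  coords <- array(rnorm(n_frames * 9, sd = 0.01), dim = c(n_frames, 3, 3))
  coords[, 2, 1] <- coords[, 2, 1] + 1.5
  coords[, 3, 2] <- coords[, 3, 2] + 2.5
  times <- seq_len(n_frames) * 0.2 # 0.2 ... 150 ns
  traj <- new_trajectory(top, coords, times)
  reg <- descriptor_registry()[1:3, ] # cheap subset: rg, rmsd, end-to-end
  d <- sample_descriptors(traj, registry = reg, start_ns = 100,
                          stride_ns = 0.2)
  expect_equal(nrow(d), 250)

  short <- new_trajectory(top, coords[1:505, , , drop = FALSE], times[1:505])
  d5 <- sample_descriptors(short, registry = reg, start_ns = 100,
                           stride_ns = 0.2)
  expect_equal(nrow(d5), 5) # 100.2 ... 101 ns

  expect_error(
    sample_descriptors(short, registry = reg, start_ns = 200),
    "101"
  )
  expect_error(
    sample_descriptors(short, registry = reg, start_ns = 100,
                       stride_ns = 0.3),
    "multiple"
  )
})
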
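# Shared fixtures and independent brute-force oracles. Oracles are written
# as plain double loops so they share no code path with the package's
# vectorized implementations.

# --- small topology builders -------------------------------------------

# n_protein protein residues (cycling donor N+HN, acceptor O, apolar CA)
# plus n_waters 3-atom waters, with deterministic-but-irregular
# coordinates; hydrogens sit ~1 Angstrom from their parent
make_mixed_system <- function(n_protein = 10, n_waters = 10, seed = 1,
                              spread = 12) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_protein)) {
    kind <- ((i - 1) %% 3) + 1
    nm <- list(c("N", "HN"), "O", "CA")[[kind]]
    el <- list(c("N", "H"), "O", "C")[[kind]]
    rows[[length(rows) + 1]] <- tibble::tibble(
      atom = nm, element = el,
      resid = i, resname = "GLY", segment = "protein",
      is_backbone = TRUE,
      charge = round(runif(length(nm), -0.5, 0.5), 3),
      eps = round(runif(length(nm), 0.02, 0.2), 3),
      rmin2 = round(runif(length(nm), 1.2, 2.2), 3),
      radius = round(runif(length(nm), 1.2, 1.9), 2)
    )
  }
  for (w in seq_len(n_waters)) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      atom = c("OW", "HW1", "HW2"), element = c("O", "H", "H"),
      resid = n_protein + w, resname = "HOH", segment = "water",
      is_backbone = FALSE,
      charge = c(-0.834, 0.417, 0.417), eps = c(0.152, 0.046, 0.046),
      rmin2 = c(1.768, 0.225, 0.225), radius = c(1.52, 1.2, 1.2)
    )
  }
  atoms <- dplyr::bind_rows(rows)
  atoms$is_acceptor <- atoms$element %in% c("O", "N")
  atoms$is_polar_h <- atoms$element == "H"
  atoms$h_parent <- NA_integer_
  for (i in which(atoms$is_polar_h)) {
    parent <- which(atoms$resid == atoms$resid[i] & atoms$element %in% c("N", "O") &
                      !atoms$is_polar_h)
    if (length(parent) > 0) atoms$h_parent[i] <- parent[1]
  }
  atoms$is_donor <- seq_len(nrow(atoms)) %in% atoms$h_parent
  top <- new_topology(atoms)
  n <- nrow(atoms)
  xyz <- matrix(runif(n * 3, -spread, spread), n, 3)
  # hydrogens sit near their parent heavy atom so geometry is bond-like
  for (h in which(top$is_polar_h)) {
    u <- rnorm(3)
    xyz[h, ] <- xyz[top$h_parent[h], ] + u / sqrt(sum(u^2))
  }
  list(top = top, xyz = xyz)
}

# --- brute-force oracles -----------------------------------------------

oracle_rg <- function(xyz, mass = rep(1, nrow(xyz))) {
  com <- c(0, 0, 0)
  for (i in seq_len(nrow(xyz))) com <- com + mass[i] * xyz[i, ]
  com <- com / sum(mass)
  s <- 0
  for (i in seq_len(nrow(xyz))) s <- s + mass[i] * sum((xyz[i, ] - com)^2)
  sqrt(s / sum(mass))
}

oracle_min_image <- function(v, box) {
  if (is.null(box)) return(v)
  v - box * round(v / box)
}

oracle_hbonds <- function(xyz, top, donors, acceptors, d_cut = 3.5,
                          angle_cut = 30, box = NULL) {
  count <- 0L
  for (h in which(top$is_polar_h)) {
    d <- top$h_parent[h]
    if (is.na(d) || !(d %in% donors)) next
    for (a in acceptors) {
      if (a == d) next
      da <- oracle_min_image(xyz[a, ] - xyz[d, ], box)
      if (sqrt(sum(da^2)) > d_cut) next
      v1 <- oracle_min_image(xyz[d, ] - xyz[h, ], box)
      v2 <- oracle_min_image(xyz[a, ] - xyz[h, ], box)
      ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (180 - ang <= angle_cut) count <- count + 1L
    }
  }
  count
}

oracle_shell <- function(xyz, top, cutoff = 3.15, box = NULL) {
  shell <- c()
  for (o in which(top$is_water_oxygen)) {
    for (b in which(top$is_backbone)) {
      v <- oracle_min_image(xyz[o, ] - xyz[b, ], box)
      if (sqrt(sum(v^2)) <= cutoff) {
        shell <- c(shell, top$resid[o])
        break
      }
    }
  }
  length(unique(shell))
}

oracle_switch <- function(r, sw, co) {
  if (r <= sw) return(1)
  if (r > co) return(0)
  ((co^2 - r^2)^2 * (co^2 + 2 * r^2 - 3 * sw^2)) / (co^2 - sw^2)^3
}

oracle_energy <- function(xyz, top, ga, gb, cutoff = 12, sw = 10, box = NULL) {
  elec <- 0
  vdw <- 0
  same <- setequal(ga, gb)
  for (ii in seq_along(ga)) {
    for (jj in seq_along(gb)) {
      i <- ga[ii]
      j <- gb[jj]
      if (same && ii >= jj) next
      if (same && abs(top$resid[i] - top$resid[j]) <= 1) next
      if (!same && i == j) next
      v <- oracle_min_image(xyz[j, ] - xyz[i, ], box)
      r <- sqrt(sum(v^2))
      if (r > cutoff || r == 0) next
      s <- oracle_switch(r, sw, cutoff)
      elec <- elec + 332.0636 * top$charge[i] * top$charge[j] / r * s
      rm <- top$rmin2[i] + top$rmin2[j]
      ep <- sqrt(top$eps[i] * top$eps[j])
      vdw <- vdw + ep * ((rm / r)^12 - 2 * (rm / r)^6) * s
    }
  }
  list(elec = elec, vdw = vdw)
}

# --- structured templates ----------------------------------------------

# two antiparallel extended strands arranged so backbone N-H...O=C bonds
# form between them
make_antiparallel_sheet <- function() {
  s1 <- build_backbone(rep(-139, 6), rep(135, 6))
  xyz1 <- s1$xyz
  rot <- function(xyz, axis, deg) {
    th <- deg * pi / 180
    R <- switch(axis,
      z = matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                 3, 3, byrow = TRUE),
      x = matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)),
                 3, 3, byrow = TRUE)
    )
    xyz %*% t(R)
  }
  xyz2 <- rot(rot(xyz1, "z", 180), "x", 180)
  xyz2 <- sweep(xyz2, 2,
                c(mean(xyz1[, 1]) - mean(xyz2[, 1]), 4, 1), "+")
  top2 <- tibble::as_tibble(s1$topology)
  top2$resid <- top2$resid + 6
  atoms <- dplyr::bind_rows(tibble::as_tibble(s1$topology), top2)
  shift <- atoms$resid > 6 & atoms$is_polar_h
  atoms$h_parent[shift] <- atoms$h_parent[shift] + nrow(xyz1)
  atoms$is_donor <- seq_len(nrow(atoms)) %in% atoms$h_parent
  list(top = new_topology(atoms), xyz = rbind(xyz1, xyz2))
}

# minimal PDB text for I/O tests
write_mini_pdb <- function(path) {
  lines <- c(
    sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            1, " N", "GLY", 1, 0, 0, 0, "N"),
    sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            2, " CA", "GLY", 1, 1.458, 0, 0, "C"),
    sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            3, " C", "GLY", 1, 2.0, 1.4, 0, "C"),
    sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            4, " O", "GLY", 1, 3.2, 1.4, 0, "O"),
    sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            5, " OH2", "HOH", 2, 6, 0, 0, "O"),
    sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            6, " H1", "HOH", 2, 6.96, 0, 0, "H"),
    sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            7, " H2", "HOH", 2, 5.76, 0.93, 0, "H"),
    "END"
  )
  writeLines(lines, path)
  path
}
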
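# Secondary-structure assignment from backbone dihedrals plus backbone
# hydrogen-bond patterns, approximating assignment schemes such as STRIDE
# or DSSP without requiring their external binaries. Also provides an
# internal-coordinate backbone builder used by tests and the synthetic
# trajectory generator.

# Idealized backbone geometry (Angstrom / degrees)
.bb_geom <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, n_h = 1.02,
  ang_c_n_ca = 121.7, ang_n_ca_c = 111.2, ang_ca_c_n = 116.2,
  ang_ca_c_o = 120.8
)

# Place atom d given a, b, c and internal coordinates: |c-d| = bond,
# angle(b, c, d) = angle, dihedral(a, b, c, d) = torsion (degrees).
.place_atom <- function(a, b, c, bond, angle, torsion) {
  angle <- angle * pi / 180
  torsion <- -torsion * pi / 180 # sign matches the .dihedral() convention
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(angle),
          bond * sin(angle) * cos(torsion),
          bond * sin(angle) * sin(torsion))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Build an idealized peptide backbone from dihedral angles
#'
#' Places N, CA, C, O and amide H atoms sequentially from idealized bond
#' lengths and angles, given per-residue phi/psi (and omega) dihedrals.
#' The amide hydrogen is positioned 1.02 Angstrom from N, antiparallel to
#' the preceding carbonyl C=O bond (the classic amide-H reconstruction);
#' the first residue carries no amide H.
#'
#' @param phi,psi Per-residue dihedrals in degrees (equal length; `phi[1]`
#'   and `psi[n]` are formally undefined and ignored).
#' @param omega Peptide-bond dihedral(s), default 180 (trans).
#' @param resname Residue name(s), recycled.
#' @return A list with `topology` (an [new_topology()] object) and `xyz`.
#' @export
build_backbone <- function(phi, psi, omega = 180, resname = "GLY") {
  n_res <- length(phi)
  stopifnot(length(psi) == n_res, n_res >= 2)
  omega <- rep(omega, length.out = n_res)
  resname <- rep(resname, length.out = n_res)
  g <- .bb_geom
  coords <- list()
  # first residue: N at origin, CA on x-axis, C in xy-plane
  N <- c(0, 0, 0)
  CA <- c(g$n_ca, 0, 0)
  ang <- g$ang_n_ca_c * pi / 180
  C <- CA + c(-g$ca_c * cos(ang), g$ca_c * sin(ang), 0)
  for (i in seq_len(n_res)) {
    if (i > 1) {
      Cprev <- coords[[i - 1]]$C
      CAprev <- coords[[i - 1]]$CA
      Nprev <- coords[[i - 1]]$N
      N <- .place_atom(Nprev, CAprev, Cprev, g$c_n, g$ang_ca_c_n, psi[i - 1])
      CA <- .place_atom(CAprev, Cprev, N, g$n_ca, g$ang_c_n_ca, omega[i - 1])
      C <- .place_atom(Cprev, N, CA, g$ca_c, g$ang_n_ca_c, phi[i])
    }
    coords[[i]] <- list(N = N, CA = CA, C = C)
  }
  # carbonyl O: in the peptide plane, anti to the next N (or to CA for the
  # C-terminal residue)
  for (i in seq_len(n_res)) {
    ref <- if (i < n_res) coords[[i + 1]]$N else NULL
    if (is.null(ref)) {
      coords[[i]]$O <- .place_atom(coords[[i]]$N, coords[[i]]$CA, coords[[i]]$C,
                                   g$c_o, g$ang_ca_c_o, psi[i] + 180)
    } else {
      u <- coords[[i]]$C - coords[[i]]$CA
      v <- coords[[i]]$C - ref
      w <- u / sqrt(sum(u^2)) + v / sqrt(sum(v^2))
      coords[[i]]$O <- coords[[i]]$C + g$c_o * w / sqrt(sum(w^2))
    }
    if (i > 1) {
      co <- coords[[i - 1]]$C - coords[[i - 1]]$O
      coords[[i]]$H <- coords[[i]]$N + g$n_h * co / sqrt(sum(co^2))
    }
  }
  rows <- list()
  xyz <- list()
  for (i in seq_len(n_res)) {
    atoms_i <- c("N", if (i > 1) "H", "CA", "C", "O")
    for (at in atoms_i) {
      rows[[length(rows) + 1]] <- tibble(
        atom = if (at == "H") "HN" else at,
        element = substr(at, 1, 1),
        resid = i, resname = resname[i], segment = "protein"
      )
      xyz[[length(xyz) + 1]] <- coords[[i]][[at]]
    }
  }
  atoms <- bind_rows(rows)
  atoms$is_backbone <- atoms$atom %in% c("N", "CA", "C", "O")
  atoms$is_acceptor <- atoms$atom == "O"
  atoms$is_polar_h <- atoms$atom == "HN"
  atoms$h_parent <- NA_integer_
  for (i in which(atoms$is_polar_h)) {
    atoms$h_parent[i] <- which(atoms$resid == atoms$resid[i] & atoms$atom == "N")
  }
  atoms$is_donor <- seq_len(nrow(atoms)) %in% atoms$h_parent
  list(topology = new_topology(atoms), xyz = do.call(rbind, xyz))
}

#' Backbone phi/psi dihedrals
#'
#' @param xyz Coordinate matrix.
#' @param topology The `elp_topology` (protein residues need N, CA, C).
#' @return A tibble with columns `resid`, `phi`, `psi` (degrees; `NA` at
#'   chain termini or where backbone atoms are missing).
#' @export
backbone_dihedrals <- function(xyz, topology) {
  prot <- topology$segment == "protein"
  resids <- sort(unique(topology$resid[prot]))
  idx_of <- function(r, at) {
    i <- which(prot & topology$resid == r & topology$atom == at)
    if (length(i) == 1) i else NA_integer_
  }
  out <- purrr::map_dfr(seq_along(resids), function(k) {
    r <- resids[k]
    iN <- idx_of(r, "N"); iCA <- idx_of(r, "CA"); iC <- idx_of(r, "C")
    phi <- psi <- NA_real_
    if (!any(is.na(c(iN, iCA, iC)))) {
      if (k > 1) {
        iCp <- idx_of(resids[k - 1], "C")
        if (!is.na(iCp)) phi <- .dihedral(xyz[iCp, ], xyz[iN, ], xyz[iCA, ], xyz[iC, ])
      }
      if (k < length(resids)) {
        iNn <- idx_of(resids[k + 1], "N")
        if (!is.na(iNn)) psi <- .dihedral(xyz[iN, ], xyz[iCA, ], xyz[iC, ], xyz[iNn, ])
      }
    }
    tibble(resid = r, phi = phi, psi = psi)
  })
  out
}

.in_helical_region <- function(phi, psi) {
  !is.na(phi) & !is.na(psi) & phi > -120 & phi < -20 & psi > -90 & psi < 30
}

.in_extended_region <- function(phi, psi) {
  !is.na(phi) & !is.na(psi) & phi > -180 & phi < -40 &
    (psi > 60 | psi < -150)
}

#' Assign per-residue secondary structure
#'
#' A dihedral-plus-hydrogen-bond-pattern assigner: backbone N-H...O=C
#' hydrogen bonds are detected with the geometric criterion of
#' [count_hbonds()] (amide hydrogens are reconstructed when absent from
#' the topology), then residues are classified as
#' * `helix`: part of an i -> i+4 hydrogen-bonded span with helical
#'   phi/psi;
#' * `sheet`: joined by a long-range (|i - j| >= 3) backbone hydrogen
#'   bond with extended phi/psi on both sides;
#' * `turn`: touched by an i -> i+3 or i -> i+4 hydrogen bond without a
#'   helical run;
#' * `coil`: everything else, including residues with missing backbone
#'   atoms (flagged by a warning).
#'
#' @param xyz Coordinate matrix.
#' @param topology The `elp_topology`.
#' @param d_cut,angle_cut Hydrogen-bond criteria (see [count_hbonds()]).
#' @return A list with `residues` (tibble: `resid`, `class`) and
#'   `fractions` (tibble: `helix`, `sheet`, `turn`, `coil`; sums to 1).
#' @export
assign_secondary_structure <- function(xyz, topology, d_cut = 3.5,
                                       angle_cut = 30) {
  prot <- topology$segment == "protein"
  resids <- sort(unique(topology$resid[prot]))
  n_res <- length(resids)
  # check backbone completeness
  complete <- vapply(resids, function(r) {
    all(c("N", "CA", "C", "O") %in% topology$atom[prot & topology$resid == r])
  }, logical(1))
  if (any(!complete)) {
    warn(sprintf("%d residue(s) missing backbone atoms; assigned coil",
                 sum(!complete)))
  }
  hb <- .backbone_hbond_pairs(xyz, topology, d_cut, angle_cut)
  cls <- rep("coil", n_res)
  pos <- match(resids, resids)
  res_pos <- setNames(seq_along(resids), resids)
  if (nrow(hb) > 0) {
    di <- res_pos[as.character(hb$donor_res)]
    ai <- res_pos[as.character(hb$acceptor_res)]
    sep <- di - ai
    dih <- backbone_dihedrals(xyz, topology)
    helical <- .in_helical_region(dih$phi, dih$psi)
    extended <- .in_extended_region(dih$phi, dih$psi)
    # helix: i -> i+4 bonds mark the spanned residues where dihedrals agree
    h45 <- which(sep == 4 | sep == 3)
    helix_marked <- rep(FALSE, n_res)
    for (k in which(sep == 4)) {
      span <- ai[k]:di[k]
      helix_marked[span] <- helix_marked[span] | helical[span]
    }
    # sheet: long-range bridges with extended dihedrals on both residues
    sheet_marked <- rep(FALSE, n_res)
    for (k in which(abs(sep) >= 3)) {
      if (sep[k] %in% c(3, 4)) next
      if (extended[di[k]] && extended[ai[k]]) {
        sheet_marked[c(di[k], ai[k])] <- TRUE
      }
    }
    turn_marked <- rep(FALSE, n_res)
    for (k in which(sep == 3 | sep == 4)) {
      turn_marked[c(di[k], ai[k])] <- TRUE
    }
    cls[turn_marked] <- "turn"
    cls[sheet_marked] <- "sheet"
    cls[helix_marked] <- "helix"
  }
  cls[!complete] <- "coil"
  fractions <- tibble(
    helix = mean(cls == "helix"), sheet = mean(cls == "sheet"),
    turn = mean(cls == "turn"), coil = mean(cls == "coil")
  )
  list(residues = tibble(resid = resids, class = cls), fractions = fractions)
}

# Backbone N-H...O hydrogen bonds as a (donor_res, acceptor_res) table.
# If the topology has no amide hydrogens, reconstruct them anti to the
# preceding carbonyl.
.backbone_hbond_pairs <- function(xyz, topology, d_cut, angle_cut) {
  prot <- which(topology$segment == "protein")
  has_h <- any(topology$is_polar_h[prot] & topology$atom[prot] %in% c("H", "HN"))
  top <- topology
  if (!has_h) {
    built <- .reconstruct_amide_h(xyz, topology)
    top <- built$topology
    xyz <- built$xyz
  }
  donors <- which(top$segment == "protein" & top$atom == "N" & top$is_donor)
  acceptors <- which(top$segment == "protein" & top$atom == "O")
  if (length(donors) == 0 || length(acceptors) == 0) {
    return(tibble(donor_res = integer(), acceptor_res = integer()))
  }
  cnt <- suppressWarnings(
    count_hbonds(xyz, top, donors, acceptors, d_cut = d_cut,
                 angle_cut = angle_cut)
  )
  pairs <- attr(cnt, "pairs")
  if (nrow(pairs) == 0) {
    return(tibble(donor_res = integer(), acceptor_res = integer()))
  }
  tibble(donor_res = top$resid[pairs$donor],
         acceptor_res = top$resid[pairs$acceptor]) %>%
    filter(.data$donor_res != .data$acceptor_res) %>%
    distinct()
}

.reconstruct_amide_h <- function(xyz, topology) {
  prot <- topology$segment == "protein"
  resids <- sort(unique(topology$resid[prot]))
  add_rows <- list()
  add_xyz <- list()
  top <- topology
  for (k in seq_along(resids)[-1]) {
    r <- resids[k]
    rp <- resids[k - 1]
    iN <- which(prot & topology$resid == r & topology$atom == "N")
    iC <- which(prot & topology$resid == rp & topology$atom == "C")
    iO <- which(prot & topology$resid == rp & topology$atom == "O")
    if (length(iN) != 1 || length(iC) != 1 || length(iO) != 1) next
    co <- xyz[iC, ] - xyz[iO, ]
    h <- xyz[iN, ] + .bb_geom$n_h * co / sqrt(sum(co^2))
    add_rows[[length(add_rows) + 1]] <- tibble(
      atom = "HN", element = "H", resid = r,
      resname = topology$resname[iN], segment = "protein",
      is_backbone = FALSE, is_acceptor = FALSE, is_polar_h = TRUE,
      h_parent = iN
    )
    add_xyz[[length(add_xyz) + 1]] <- h
  }
  if (length(add_rows) == 0) return(list(topology = topology, xyz = xyz))
  new_atoms <- bind_rows(as_tibble(topology)[, ], bind_rows(add_rows))
  new_atoms$is_donor <- seq_len(nrow(new_atoms)) %in% new_atoms$h_parent
  list(
    topology = new_topology(new_atoms),
    xyz = rbind(xyz, do.call(rbind, add_xyz))
  )
}
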
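# Per-frame molecular property calculations. All distances in Angstrom,
# energies in kcal/mol. Pairwise operations use direct vectorized distance
# matrices; when periodic box lengths are supplied the minimum-image
# convention is applied per dimension.

# Coulomb constant in kcal*Angstrom/(mol*e^2)
.coulomb_k <- 332.0636

# Pairwise displacement with optional minimum image. a: n x 3, b: m x 3.
# Returns list(dx, dy, dz, d) of n x m matrices.
.pair_dist <- function(a, b, box = NULL) {
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  dz <- outer(a[, 3], b[, 3], "-")
  if (!is.null(box)) {
    dx <- dx - box[1] * round(dx / box[1])
    dy <- dy - box[2] * round(dy / box[2])
    dz <- dz - box[3] * round(dz / box[3])
  }
  list(dx = dx, dy = dy, dz = dz, d = sqrt(dx^2 + dy^2 + dz^2))
}

#' Radius of gyration
#'
#' Mass-weighted (or geometric) root-mean-square distance of the selected
#' atoms from their centre of mass. Invariant to rigid-body motion.
#'
#' @param xyz An `n_atoms x 3` coordinate matrix (Angstrom).
#' @param sel Integer indices of the atoms to include (default all).
#' @param mass Per-atom masses for the selection; `NULL` weights all atoms
#'   equally.
#' @return Radius of gyration in Angstrom.
#' @export
#' @examples
#' radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0)))
radius_of_gyration <- function(xyz, sel = NULL, mass = NULL) {
  if (!is.null(sel)) xyz <- xyz[sel, , drop = FALSE]
  if (nrow(xyz) == 0) abort("Empty selection")
  if (is.null(mass)) mass <- rep(1, nrow(xyz))
  stopifnot(length(mass) == nrow(xyz))
  com <- colSums(xyz * mass) / sum(mass)
  dev <- sweep(xyz, 2, com)
  sqrt(sum(mass * rowSums(dev^2)) / sum(mass))
}

# Gyration-tensor asphericity in [0, 1]: 0 for a sphere, 1 for a rod.
.asphericity <- function(xyz) {
  dev <- sweep(xyz, 2, colMeans(xyz))
  gyr <- crossprod(dev) / nrow(xyz)
  ev <- sort(eigen(gyr, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  tr <- sum(ev)
  if (tr <= 0) return(0)
  (ev[1] - 0.5 * (ev[2] + ev[3])) / tr # 0 = sphere, 1 = rod
}

#' Minimal RMSD after optimal superposition (Kabsch)
#'
#' Least-squares superposes `xyz` onto `ref` over proper rotations and
#' translations (Kabsch algorithm with determinant correction to exclude
#' reflections) and returns the residual RMSD. A degenerate (collinear or
#' fewer than 3 atoms) reference cannot fix a rotation; in that case the
#' centroids are superposed only and the result is flagged with attribute
#' `degenerate = TRUE` and a warning.
#'
#' @param xyz,ref `n x 3` coordinate matrices with matching atom order.
#' @param sel Optional indices applied to both.
#' @return RMSD in Angstrom.
#' @export
rmsd_superposed <- function(xyz, ref, sel = NULL) {
  if (!is.null(sel)) {
    xyz <- xyz[sel, , drop = FALSE]
    ref <- ref[sel, , drop = FALSE]
  }
  if (nrow(xyz) != nrow(ref)) abort("Selections must have equal atom counts")
  n <- nrow(xyz)
  x <- sweep(xyz, 2, colMeans(xyz))
  y <- sweep(ref, 2, colMeans(ref))
  degenerate <- n < 3 || {
    s <- svd(y)$d
    sum(s > max(s) * 1e-8) < 2
  }
  if (degenerate) {
    warn("Degenerate reference geometry: translation-only superposition")
    out <- sqrt(sum((x - y)^2) / n)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  s <- svd(crossprod(x, y))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  out <- sqrt(sum((x %*% t(rot) - y)^2) / n)
  attr(out, "degenerate") <- FALSE
  out
}

#' Count geometric hydrogen bonds
#'
#' A (D, H, A) triple is a hydrogen bond when the donor-acceptor distance
#' is at most `d_cut` and the D-H-A angle deviates from linearity (180
#' degrees) by at most `angle_cut`, i.e. the angle at the hydrogen is at
#' least `180 - angle_cut` degrees. Donors without an attached hydrogen in
#' the topology are skipped (their number is reported in attribute
#' `skipped_donors` with a warning).
#'
#' @param xyz Coordinate matrix for the whole system.
#' @param topology The `elp_topology`.
#' @param donors Indices of donor heavy atoms to consider.
#' @param acceptors Indices of acceptor atoms to consider.
#' @param d_cut Donor-acceptor distance cutoff, Angstrom (default 3.5).
#' @param angle_cut Deviation-from-linearity cutoff at H, degrees
#'   (default 30).
#' @param box Optional periodic box edge lengths (length 3).
#' @return Integer count; attribute `pairs` holds a tibble of the
#'   contributing (donor, hydrogen, acceptor) index triples.
#' @export
count_hbonds <- function(xyz, topology, donors, acceptors,
                         d_cut = 3.5, angle_cut = 30, box = NULL) {
  donors <- unique(donors)
  acceptors <- unique(acceptors)
  hyd <- which(topology$is_polar_h & topology$h_parent %in% donors)
  have_h <- unique(topology$h_parent[hyd])
  skipped <- setdiff(donors, have_h)
  if (length(skipped) > 0) {
    warn(sprintf("%d donor(s) without an attached hydrogen were skipped",
                 length(skipped)))
  }
  if (length(hyd) == 0 || length(acceptors) == 0) {
    out <- 0L
    attr(out, "skipped_donors") <- length(skipped)
    attr(out, "pairs") <- tibble(donor = integer(), hydrogen = integer(),
                                 acceptor = integer())
    return(out)
  }
  d_idx <- topology$h_parent[hyd]
  pd_da <- .pair_dist(xyz[d_idx, , drop = FALSE],
                      xyz[acceptors, , drop = FALSE], box)$d
  # exclude the donor itself as acceptor
  self <- outer(d_idx, acceptors, "==")
  cand <- which(pd_da <= d_cut & !self, arr.ind = TRUE)
  n_bonds <- 0L
  rows <- list()
  if (nrow(cand) > 0) {
    for (r in seq_len(nrow(cand))) {
      hi <- hyd[cand[r, 1]]
      di <- d_idx[cand[r, 1]]
      ai <- acceptors[cand[r, 2]]
      v1 <- xyz[di, ] - xyz[hi, ]
      v2 <- xyz[ai, ] - xyz[hi, ]
      if (!is.null(box)) {
        v1 <- v1 - box * round(v1 / box)
        v2 <- v2 - box * round(v2 / box)
      }
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      if (180 - ang <= angle_cut) {
        n_bonds <- n_bonds + 1L
        rows[[length(rows) + 1]] <- c(di, hi, ai)
      }
    }
  }
  out <- n_bonds
  attr(out, "skipped_donors") <- length(skipped)
  attr(out, "pairs") <- if (length(rows) > 0) {
    m <- do.call(rbind, rows)
    tibble(donor = m[, 1], hydrogen = m[, 2], acceptor = m[, 3])
  } else {
    tibble(donor = integer(), hydrogen = integer(), acceptor = integer())
  }
  out
}

# Deterministic quasi-uniform points on the unit sphere (golden-spiral
# lattice); avoids RNG so SASA is reproducible.
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-atom solvent accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere over the atomic vdW surfaces: each atom's surface
#' is sampled with a deterministic quasi-uniform point lattice at radius
#' `r_i + probe` and the accessible fraction is the share of points not
#' buried inside any neighbour's probe-expanded sphere.
#'
#' @param xyz Coordinate matrix.
#' @param radii Per-atom vdW radii (Angstrom).
#' @param sel Indices of atoms whose area to compute; all atoms in `xyz`
#'   act as potential occluders.
#' @param probe Probe radius, Angstrom (default 1.4, a water probe).
#' @param n_points Surface points per atom (default 240).
#' @return Numeric vector of per-atom areas (Angstrom^2) for `sel`.
#' @export
sasa_atoms <- function(xyz, radii, sel = NULL, probe = 1.4, n_points = 240) {
  stopifnot(nrow(xyz) == length(radii))
  if (any(!is.finite(radii) | radii <= 0)) abort("All atoms need a positive radius")
  if (is.null(sel)) sel <- seq_len(nrow(xyz))
  pts <- .sphere_points(n_points)
  ext <- radii + probe
  areas <- numeric(length(sel))
  for (k in seq_along(sel)) {
    i <- sel[k]
    ri <- ext[i]
    surf <- sweep(pts * ri, 2, xyz[i, ], "+")
    # neighbours whose expanded spheres can reach atom i's surface
    d_in <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(d_in < ri + ext & seq_len(nrow(xyz)) != i)
    # coincident duplicate atoms occlude each other's surface entirely
    # except one representative (keep the first)
    dup <- nb[d_in[nb] < 1e-9 & ext[nb] >= ri]
    if (any(dup < i)) {
      areas[k] <- 0
      next
    }
    nb <- setdiff(nb, dup)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj <- sqrt(colSums((t(surf) - xyz[j, ])^2))
      acc <- acc & dj >= ext[j]
      if (!any(acc)) break
    }
    areas[k] <- 4 * pi * ri^2 * sum(acc) / n_points
  }
  areas
}

#' Total, hydrophobic and hydrophilic SASA
#'
#' Computes the Shrake-Rupley SASA of the protein and partitions it by
#' residue hydropathy: atoms in residues with a positive Kyte-Doolittle
#' value count as hydrophobic, the rest as hydrophilic, so the two classes
#' always sum to the total.
#'
#' @inheritParams sasa_atoms
#' @param topology The `elp_topology`; protein atoms are selected.
#' @return A tibble with columns `total`, `hydrophobic`, `hydrophilic`,
#'   `backbone`, `sidechain` (Angstrom^2).
#' @export
sasa <- function(xyz, topology, probe = 1.4, n_points = 240) {
  sel <- which(topology$segment == "protein")
  if (length(sel) == 0) abort("No protein atoms in topology")
  areas <- sasa_atoms(xyz, topology$radius, sel = sel,
                      probe = probe, n_points = n_points)
  res_letter <- .resname_to_letter(topology$resname[sel])
  kd_val <- .kd[res_letter]
  kd_val[is.na(kd_val)] <- 0
  hydrophobic <- sum(areas[kd_val > 0])
  bb <- topology$is_backbone[sel]
  tibble(
    total = sum(areas),
    hydrophobic = hydrophobic,
    hydrophilic = sum(areas) - hydrophobic,
    backbone = sum(areas[bb]),
    sidechain = sum(areas[!bb])
  )
}

.three_to_one <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLU = "E",
  GLN = "Q", GLY = "G", HIS = "H", HSD = "H", HSE = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P", SER = "S",
  THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

.resname_to_letter <- function(resname) {
  out <- .three_to_one[toupper(resname)]
  one <- toupper(resname) %in% names(.kd)
  out[one] <- toupper(resname)[one]
  out
}

#' Count hydration-shell water molecules
#'
#' Number of water molecules whose oxygen lies within `cutoff` of any
#' backbone atom; each water is counted once.
#'
#' @param xyz Coordinate matrix.
#' @param topology The `elp_topology`.
#' @param cutoff Shell cutoff from the backbone, Angstrom (default 3.15).
#' @param box Optional periodic box edge lengths.
#' @return Integer count; attribute `water_resid` lists the residue
#'   indices of shell waters.
#' @export
hydration_shell_waters <- function(xyz, topology, cutoff = 3.15, box = NULL) {
  bb <- which(topology$is_backbone)
  wo <- which(topology$is_water_oxygen)
  if (length(wo) == 0) {
    warn("No waters in topology; hydration shell is empty")
    out <- 0L
    attr(out, "water_resid") <- integer()
    return(out)
  }
  if (length(bb) == 0) abort("No backbone atoms in topology")
  d <- .pair_dist(xyz[wo, , drop = FALSE], xyz[bb, , drop = FALSE], box)$d
  in_shell <- apply(d <= cutoff, 1, any)
  out <- length(unique(topology$resid[wo][in_shell]))
  attr(out, "water_resid") <- unique(topology$resid[wo][in_shell])
  out
}

# CHARMM-style energy switching function on [switch, cutoff].
.switch_fn <- function(r, switch, cutoff) {
  s <- rep(1, length(r))
  mid <- r > switch & r <= cutoff
  r2 <- r[mid]^2
  c2 <- cutoff^2
  s2 <- switch^2
  s[mid] <- ((c2 - r2)^2 * (c2 + 2 * r2 - 3 * s2)) / (c2 - s2)^3
  s[r > cutoff] <- 0
  s
}

#' Pairwise nonbonded interaction energies
#'
#' Coulomb (`332.0636 q_i q_j / r`) and Lennard-Jones
#' (`eps_ij [(rmin_ij/r)^12 - 2 (rmin_ij/r)^6]`, Lorentz-Berthelot-style
#' CHARMM combination: `eps_ij = sqrt(eps_i eps_j)`,
#' `rmin_ij = rmin2_i + rmin2_j`) sums with an energy switching function
#' applied between `switch` and `cutoff`. When the two groups differ, only
#' cross-group pairs contribute; for a single group, unique pairs `i < j`
#' contribute, excluding pairs within the same or adjacent residues (an
#' analysis-level stand-in for bonded 1-2/1-3 exclusions).
#'
#' @param xyz Coordinate matrix.
#' @param topology The `elp_topology` (supplies `charge`, `eps`, `rmin2`,
#'   `resid`).
#' @param group_a,group_b Atom index vectors. Equal (identical sets) for an
#'   intra-group energy.
#' @param cutoff Interaction cutoff, Angstrom (default 12).
#' @param switch Switching distance, Angstrom (default 10).
#' @param box Optional periodic box edge lengths.
#' @return A tibble with columns `electrostatic` and `vdw` (kcal/mol).
#' @export
nonbonded_energy <- function(xyz, topology, group_a, group_b,
                             cutoff = 12, switch = 10, box = NULL) {
  q <- topology$charge
  eps <- topology$eps
  rmin2 <- topology$rmin2
  if (any(is.na(q[c(group_a, group_b)])) ||
      any(is.na(eps[c(group_a, group_b)])) ||
      any(is.na(rmin2[c(group_a, group_b)]))) {
    abort("Missing nonbonded parameters (charge/eps/rmin2) for selected atoms")
  }
  same_group <- setequal(group_a, group_b)
  pd <- .pair_dist(xyz[group_a, , drop = FALSE],
                   xyz[group_b, , drop = FALSE], box)
  d <- pd$d
  keep <- d <= cutoff & d > 0
  if (same_group) {
    idx <- outer(seq_along(group_a), seq_along(group_b), "<")
    near_res <- abs(outer(topology$resid[group_a], topology$resid[group_b], "-")) <= 1
    keep <- keep & idx & !near_res
  } else {
    overlap <- outer(group_a, group_b, "==")
    keep <- keep & !overlap
  }
  if (!any(keep)) return(tibble(electrostatic = 0, vdw = 0))
  r <- d[keep]
  sw <- .switch_fn(r, switch, cutoff)
  qq <- outer(q[group_a], q[group_b])[keep]
  elec <- sum(.coulomb_k * qq / r * sw)
  eij <- sqrt(outer(eps[group_a], eps[group_b]))[keep]
  rij <- outer(rmin2[group_a], rmin2[group_b], "+")[keep]
  ratio6 <- (rij / r)^6
  vdw <- sum(eij * (ratio6^2 - 2 * ratio6) * sw)
  tibble(electrostatic = elec, vdw = vdw)
}

#' End-to-end distance of the protein chain
#'
#' Distance between the first and last alpha-carbon (falling back to the
#' first and last protein atom when no CA atoms are named).
#'
#' @param xyz Coordinate matrix.
#' @param topology The `elp_topology`.
#' @return Distance in Angstrom.
#' @export
end_to_end_distance <- function(xyz, topology) {
  ca <- which(topology$segment == "protein" & topology$atom == "CA")
  if (length(ca) < 2) ca <- which(topology$segment == "protein")
  if (length(ca) < 2) abort("Need at least two protein atoms")
  sqrt(sum((xyz[ca[1], ] - xyz[ca[length(ca)], ])^2))
}
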
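# The 27-descriptor registry and per-frame featurization. The registry is
# plain data (a tibble of name/unit/extractor), so an alternative property
# list can be swapped in without touching the sampling code.

#' The default 27-descriptor registry
#'
#' Ordered table of the 27 molecular properties sampled per trajectory
#' frame: intrapeptide and peptide-solvent hydrogen bonding (with
#' backbone/side-chain and hydration-layer splits), radius of gyration,
#' superposed backbone RMSD, end-to-end distance, total/hydrophobic/
#' hydrophilic/backbone/side-chain SASA, hydration-shell water count,
#' secondary-structure fractions, and switched electrostatic/van der Waals
#' interaction energies (intrapeptide and peptide-solvent, plus their
#' totals), completed by two shape descriptors (asphericity, maximum CA-CA
#' extent). Each row carries an `extract` function that pulls the value
#' from the per-frame context computed by [frame_descriptors()].
#'
#' @return A 27-row tibble with columns `name`, `unit`, `extract`.
#' @export
descriptor_registry <- function() {
  reg <- tribble_registry()
  stopifnot(nrow(reg) == 27, !anyDuplicated(reg$name))
  reg
}

tribble_registry <- function() {
  e <- function(f) list(f)
  tibble(
    name = c(
      "rg", "rmsd_backbone", "end_to_end",
      "sasa_total", "sasa_hydrophobic", "sasa_hydrophilic",
      "sasa_backbone", "sasa_sidechain",
      "hbonds_intra", "hbonds_intra_bb_bb", "hbonds_intra_bb_sc",
      "hbonds_intra_sc_sc",
      "hbonds_elp_water", "hbonds_elp_shell", "hydration_waters",
      "helix_frac", "sheet_frac", "turn_frac", "coil_frac",
      "elec_intra", "vdw_intra", "elec_elp_water", "vdw_elp_water",
      "nonbonded_intra", "nonbonded_elp_water",
      "asphericity", "max_extent"
    ),
    unit = c(
      "Angstrom", "Angstrom", "Angstrom",
      "Angstrom^2", "Angstrom^2", "Angstrom^2", "Angstrom^2", "Angstrom^2",
      "count", "count", "count", "count",
      "count", "count", "count",
      "fraction", "fraction", "fraction", "fraction",
      "kcal/mol", "kcal/mol", "kcal/mol", "kcal/mol",
      "kcal/mol", "kcal/mol",
      "dimensionless", "Angstrom"
    ),
    extract = c(
      e(function(ctx) ctx$rg),
      e(function(ctx) ctx$rmsd),
      e(function(ctx) ctx$end_to_end),
      e(function(ctx) ctx$sasa$total),
      e(function(ctx) ctx$sasa$hydrophobic),
      e(function(ctx) ctx$sasa$hydrophilic),
      e(function(ctx) ctx$sasa$backbone),
      e(function(ctx) ctx$sasa$sidechain),
      e(function(ctx) ctx$hb_intra),
      e(function(ctx) ctx$hb_intra_bb_bb),
      e(function(ctx) ctx$hb_intra_bb_sc),
      e(function(ctx) ctx$hb_intra_sc_sc),
      e(function(ctx) ctx$hb_water),
      e(function(ctx) ctx$hb_shell),
      e(function(ctx) ctx$hydration_waters),
      e(function(ctx) ctx$ss$helix),
      e(function(ctx) ctx$ss$sheet),
      e(function(ctx) ctx$ss$turn),
      e(function(ctx) ctx$ss$coil),
      e(function(ctx) ctx$en_intra$electrostatic),
      e(function(ctx) ctx$en_intra$vdw),
      e(function(ctx) ctx$en_water$electrostatic),
      e(function(ctx) ctx$en_water$vdw),
      e(function(ctx) ctx$en_intra$electrostatic + ctx$en_intra$vdw),
      e(function(ctx) ctx$en_water$electrostatic + ctx$en_water$vdw),
      e(function(ctx) ctx$asphericity),
      e(function(ctx) ctx$max_extent)
    )
  )
}

#' Compute all descriptors for one frame
#'
#' Builds the shared per-frame context (selections, SASA, hydrogen-bond
#' sets, secondary structure, energies) once, then evaluates every
#' registry extractor against it.
#'
#' @param xyz Frame coordinate matrix.
#' @param topology The `elp_topology`.
#' @param ref_xyz Reference coordinates for the backbone RMSD (typically
#'   the first sampled frame).
#' @param registry Descriptor registry (default [descriptor_registry()]).
#' @param box Optional periodic box edge lengths for this frame.
#' @param sasa_points Sphere points per atom for the SASA estimate.
#' @return A named numeric vector, one entry per registry row.
#' @export
frame_descriptors <- function(xyz, topology, ref_xyz,
                              registry = descriptor_registry(),
                              box = NULL, sasa_points = 120) {
  prot <- which(topology$segment == "protein")
  bb <- which(topology$is_backbone)
  ca <- which(topology$segment == "protein" & topology$atom == "CA")
  mass <- topology$mass[prot]

  ctx <- list()
  ctx$rg <- radius_of_gyration(xyz, sel = prot, mass = mass)
  ctx$rmsd <- as.numeric(rmsd_superposed(xyz, ref_xyz, sel = bb))
  ctx$end_to_end <- end_to_end_distance(xyz, topology)
  ctx$sasa <- sasa(xyz, topology, n_points = sasa_points)
  ctx$asphericity <- .asphericity(xyz[prot, , drop = FALSE])
  ext_sel <- if (length(ca) >= 2) ca else prot
  pd <- .pair_dist(xyz[ext_sel, , drop = FALSE], xyz[ext_sel, , drop = FALSE])
  ctx$max_extent <- max(pd$d)

  don_p <- which(topology$is_donor & topology$segment == "protein")
  acc_p <- which(topology$is_acceptor & topology$segment == "protein")
  hb_all <- suppressWarnings(
    count_hbonds(xyz, topology, don_p, acc_p, box = box)
  )
  ctx$hb_intra <- as.integer(hb_all)
  pairs <- attr(hb_all, "pairs")
  d_bb <- topology$is_backbone[pairs$donor]
  a_bb <- topology$is_backbone[pairs$acceptor]
  ctx$hb_intra_bb_bb <- sum(d_bb & a_bb)
  ctx$hb_intra_sc_sc <- sum(!d_bb & !a_bb)
  ctx$hb_intra_bb_sc <- nrow(pairs) - ctx$hb_intra_bb_bb - ctx$hb_intra_sc_sc

  wat <- which(topology$segment == "water")
  don_w <- which(topology$is_donor & topology$segment == "water")
  acc_w <- which(topology$is_acceptor & topology$segment == "water")
  hw <- suppressWarnings(hydration_shell_waters(xyz, topology, box = box))
  ctx$hydration_waters <- as.integer(hw)
  if (length(wat) > 0) {
    hb_pw <- suppressWarnings(
      count_hbonds(xyz, topology, don_p, acc_w, box = box)
    )
    hb_wp <- suppressWarnings(
      count_hbonds(xyz, topology, don_w, acc_p, box = box)
    )
    ctx$hb_water <- as.integer(hb_pw) + as.integer(hb_wp)
    shell_res <- attr(hw, "water_resid")
    in_shell <- topology$resid %in% shell_res & topology$segment == "water"
    don_s <- intersect(don_w, which(in_shell))
    acc_s <- intersect(acc_w, which(in_shell))
    hb_ps <- suppressWarnings(
      count_hbonds(xyz, topology, don_p, acc_s, box = box)
    )
    hb_sp <- suppressWarnings(
      count_hbonds(xyz, topology, don_s, acc_p, box = box)
    )
    ctx$hb_shell <- as.integer(hb_ps) + as.integer(hb_sp)
    ctx$en_water <- nonbonded_energy(xyz, topology, prot, wat, box = box)
  } else {
    ctx$hb_water <- 0L
    ctx$hb_shell <- 0L
    ctx$en_water <- tibble(electrostatic = 0, vdw = 0)
  }
  ctx$en_intra <- nonbonded_energy(xyz, topology, prot, prot, box = box)
  ctx$ss <- suppressWarnings(
    assign_secondary_structure(xyz, topology)$fractions
  )

  vals <- vapply(registry$extract, function(f) as.numeric(f(ctx)), numeric(1))
  setNames(vals, registry$name)
}

#' Sample a descriptor table from a trajectory
#'
#' Selects frames after the equilibration window (`time > start_ns`) at a
#' fixed stride and computes the full registry per frame. A 100-150 ns
#' window at a 0.2 ns stride yields exactly 250 records per replica. The
#' stride must be commensurate with the trajectory's frame spacing.
#'
#' @param traj An `elp_trajectory`.
#' @param registry Descriptor registry (default [descriptor_registry()]).
#' @param start_ns Equilibration cutoff; frames at `time > start_ns` are
#'   sampled (default 100).
#' @param stride_ns Sampling stride in ns (default 0.2).
#' @param sasa_points Sphere points per atom for the SASA estimate.
#' @return A tibble with columns `elp`, `replica`, `time_ns` and one
#'   column per registry descriptor.
#' @export
sample_descriptors <- function(traj, registry = descriptor_registry(),
                               start_ns = 100, stride_ns = 0.2,
                               sasa_points = 120) {
  stopifnot(inherits(traj, "elp_trajectory"))
  times <- traj$times
  if (max(times) < start_ns) {
    abort(sprintf(
      "Trajectory spans only %.3f-%.3f ns; cannot sample after start_ns = %g",
      min(times), max(times), start_ns
    ))
  }
  if (length(times) > 1) {
    dt <- diff(times)
    if (max(abs(dt - dt[1])) > 1e-9) abort("Frame spacing must be uniform")
    ratio <- stride_ns / dt[1]
    if (abs(ratio - round(ratio)) > 1e-6 || round(ratio) < 1) {
      abort(sprintf(
        "stride_ns = %g is not a multiple of the frame spacing %g ns",
        stride_ns, dt[1]
      ))
    }
    step <- as.integer(round(ratio))
  } else {
    step <- 1L
  }
  eligible <- which(times > start_ns + 1e-9)
  sel <- eligible[seq(1, length(eligible), by = step)]
  if (length(sel) == 0) abort("No frames fall in the sampling window")
  ref_xyz <- frame_coords(traj, sel[1])
  purrr::map_dfr(sel, function(f) {
    xyz <- frame_coords(traj, f)
    box <- if (is.null(traj$box)) NULL else traj$box[f, ]
    vals <- frame_descriptors(xyz, traj$topology, ref_xyz,
                              registry = registry, box = box,
                              sasa_points = sasa_points)
    dplyr::bind_cols(
      tibble(elp = traj$elp, replica = traj$replica, time_ns = times[f]),
      as_tibble(as.list(vals))
    )
  })
}
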
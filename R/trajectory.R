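# Trajectory containers and I/O. A topology is a per-atom tibble; a
# trajectory couples it with a frames x atoms x 3 coordinate array (in
# Angstrom) and per-frame times (in ns).

#' Construct a topology
#'
#' A topology is a per-atom table carrying everything the descriptor
#' calculations need: names, residue assignment, segment class
#' (protein/water/ion), donor/acceptor flags and nonbonded parameters.
#'
#' @param atoms A data frame with at least columns `atom` (name), `element`,
#'   `resid` (1-based residue index), `resname` and `segment` (one of
#'   `"protein"`, `"water"`, `"ion"`). Optional columns: `radius` (vdW
#'   radius, Angstrom), `charge` (e), `eps` (LJ well depth, kcal/mol),
#'   `rmin2` (LJ rmin/2, Angstrom), `mass` (amu), `is_backbone`,
#'   `is_donor`, `is_acceptor`, `is_polar_h`, and `h_parent` (for polar
#'   hydrogens, the row index of the bonded donor heavy atom). Missing
#'   flag/parameter columns are filled with conservative defaults.
#' @return A tibble of class `elp_topology`.
#' @export
new_topology <- function(atoms) {
  atoms <- as_tibble(atoms)
  required <- c("atom", "element", "resid", "resname", "segment")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("Topology is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!all(atoms$segment %in% c("protein", "water", "ion"))) {
    abort("`segment` must be one of 'protein', 'water', 'ion'")
  }
  defaults <- list(
    radius = NA_real_, charge = 0, eps = 0, rmin2 = 0,
    mass = NA_real_,
    is_backbone = FALSE, is_donor = FALSE, is_acceptor = FALSE,
    is_polar_h = FALSE, h_parent = NA_integer_
  )
  for (nm in names(defaults)) {
    if (!nm %in% names(atoms)) atoms[[nm]] <- defaults[[nm]]
  }
  if (!"is_water_oxygen" %in% names(atoms)) {
    atoms$is_water_oxygen <- atoms$segment == "water" & toupper(atoms$element) == "O"
  }
  if (any(is.na(atoms$mass))) {
    atoms$mass <- ifelse(is.na(atoms$mass), .element_mass(atoms$element), atoms$mass)
  }
  if (any(is.na(atoms$radius))) {
    atoms$radius <- ifelse(is.na(atoms$radius), .element_radius(atoms$element), atoms$radius)
  }
  if (any(atoms$radius <= 0, na.rm = TRUE)) abort("Atomic radii must be positive")
  wat <- atoms$resid[atoms$segment == "water"]
  if (length(wat) > 0 && any(table(wat) != 3)) {
    abort("Each water must have exactly 3 atoms (O, H, H)")
  }
  ph <- which(atoms$is_polar_h)
  if (length(ph) > 0 && any(is.na(atoms$h_parent[ph]))) {
    abort("Every polar hydrogen needs an `h_parent` donor heavy atom index")
  }
  class(atoms) <- c("elp_topology", class(atoms))
  atoms
}

.element_mass <- function(element) {
  masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
              NA. = 22.990, CL = 35.45)
  out <- masses[toupper(element)]
  ifelse(is.na(out), 12.011, out)
}

.element_radius <- function(element) {
  radii <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.52, S = 1.8,
             NA. = 2.27, CL = 1.75)
  out <- radii[toupper(element)]
  ifelse(is.na(out), 1.7, out)
}

#' Construct a trajectory
#'
#' @param topology An `elp_topology`.
#' @param coords A numeric array of dimension `n_frames x n_atoms x 3`
#'   (Angstrom), or a single `n_atoms x 3` matrix for a one-frame
#'   trajectory.
#' @param times Frame times in ns, strictly increasing, one per frame.
#' @param box Optional per-frame periodic box edge lengths: an
#'   `n_frames x 3` matrix (or length-3 vector recycled to all frames).
#'   `NULL` means open boundaries.
#' @param elp,replica Optional identifiers carried into descriptor tables.
#' @return An object of class `elp_trajectory`.
#' @export
new_trajectory <- function(topology, coords, times, box = NULL,
                           elp = "elp", replica = 1L) {
  stopifnot(inherits(topology, "elp_topology"))
  if (is.matrix(coords)) coords <- array(coords, dim = c(1, dim(coords)))
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  if (dim(coords)[2] != nrow(topology)) {
    abort("Coordinate atom count does not match topology")
  }
  if (dim(coords)[1] != length(times)) abort("Frame count must equal time count")
  if (length(times) > 1 && any(diff(times) <= 0)) {
    abort("Frame times must be strictly increasing")
  }
  if (!all(is.finite(coords))) abort("Coordinates must be finite")
  if (!is.null(box)) {
    if (is.null(dim(box))) box <- matrix(box, nrow = dim(coords)[1], ncol = 3, byrow = TRUE)
    stopifnot(nrow(box) == dim(coords)[1], ncol(box) == 3)
  }
  structure(
    list(topology = topology, coords = coords, times = as.numeric(times),
         box = box, elp = elp, replica = replica),
    class = "elp_trajectory"
  )
}

#' @export
print.elp_trajectory <- function(x, ...) {
  cat(sprintf(
    "<elp_trajectory> %s replica %s: %d frames, %d atoms, %.3f-%.3f ns%s\n",
    x$elp, x$replica, dim(x$coords)[1], dim(x$coords)[2],
    min(x$times), max(x$times),
    if (is.null(x$box)) ", open boundaries" else ", periodic"
  ))
  invisible(x)
}

#' Extract one frame's coordinates
#'
#' @param traj An `elp_trajectory`.
#' @param i Frame index.
#' @return An `n_atoms x 3` numeric matrix.
#' @export
frame_coords <- function(traj, i) {
  stopifnot(inherits(traj, "elp_trajectory"), i >= 1, i <= dim(traj$coords)[1])
  matrix(traj$coords[i, , ], ncol = 3)
}

#' Read a topology from a PDB file
#'
#' Parses the PDB with `bio3d`, classifies segments by residue name (water
#' residues `HOH`/`TIP3`/`WAT`/`SOL`; ions `NA`/`CL`/`SOD`/`CLA`; all else
#' protein), derives backbone and donor/acceptor flags from atom names, and
#' optionally merges a sidecar nonbonded parameter table.
#'
#' @param path PDB file path.
#' @param params Optional parameter table (see [read_param_table()]) or a
#'   path to one: columns `resname`, `atom`, `charge`, `eps`, `rmin2`,
#'   `radius`, joined by atom and residue name.
#' @return An `elp_topology`.
#' @export
read_topology_pdb <- function(path, params = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    abort("Package 'bio3d' is required to read PDB files")
  }
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  resname <- a$resid # bio3d: `resid` is the residue NAME, `resno` the number
  water_res <- c("HOH", "TIP3", "WAT", "SOL")
  ion_res <- c("NA", "CL", "SOD", "CLA", "K", "POT", "MG", "CA2")
  segment <- case_when(
    resname %in% water_res ~ "water",
    resname %in% ion_res ~ "ion",
    TRUE ~ "protein"
  )
  element <- ifelse(!is.na(a$elesy) & nzchar(a$elesy), a$elesy,
                    substr(gsub("[0-9]", "", a$elety), 1, 1))
  atoms <- tibble(
    atom = a$elety, element = toupper(element),
    resid = as.integer(a$resno), resname = resname, segment = segment
  )
  atoms <- .annotate_atoms(atoms)
  if (!is.null(params)) {
    if (is.character(params)) params <- read_param_table(params)
    atoms <- .merge_params(atoms, params)
  }
  top <- new_topology(atoms)
  attr(top, "xyz") <- matrix(c(a$x, a$y, a$z), ncol = 3)
  top
}

# Derive backbone/donor/acceptor/polar-H flags from atom naming
# conventions; polar hydrogens are matched to the nearest preceding donor
# heavy atom within the same residue.
.annotate_atoms <- function(atoms) {
  atoms$is_backbone <- atoms$segment == "protein" &
    atoms$atom %in% c("N", "CA", "C", "O", "OXT")
  atoms$is_water_oxygen <- atoms$segment == "water" & atoms$element == "O"
  atoms$is_acceptor <- atoms$element %in% c("O", "N") & atoms$segment != "ion"
  atoms$is_polar_h <- atoms$element == "H" &
    atoms$atom %in% c("H", "HN", "H1", "H2", "H3", "HE", "HZ1", "HZ2", "HZ3",
                      "HH11", "HH12", "HH21", "HH22", "HG1", "HH", "HD1",
                      "HE1", "HE2", "HW1", "HW2", "OH2H1", "OH2H2") |
    (atoms$segment == "water" & atoms$element == "H")
  atoms$h_parent <- NA_integer_
  heavy_names <- list(
    H = "N", HN = "N", H1 = "N", H2 = "N", H3 = "N",
    HZ1 = "NZ", HZ2 = "NZ", HZ3 = "NZ", HG1 = "OG1", HH = "OH",
    HE = "NE", HD1 = "ND1", HE1 = "NE1", HE2 = "NE2"
  )
  for (i in which(atoms$is_polar_h)) {
    same_res <- which(atoms$resid == atoms$resid[i] & atoms$segment == atoms$segment[i])
    if (atoms$segment[i] == "water") {
      ox <- same_res[atoms$element[same_res] == "O"]
      if (length(ox) >= 1) atoms$h_parent[i] <- ox[1]
    } else {
      target <- heavy_names[[atoms$atom[i]]]
      cand <- if (!is.null(target)) same_res[atoms$atom[same_res] == target] else integer()
      if (length(cand) >= 1) atoms$h_parent[i] <- cand[1]
    }
  }
  atoms$is_donor <- seq_len(nrow(atoms)) %in% atoms$h_parent
  atoms
}

.merge_params <- function(atoms, params) {
  params <- as_tibble(params)
  keep <- intersect(c("charge", "eps", "rmin2", "radius", "mass"), names(params))
  for (nm in keep) if (nm %in% names(atoms)) atoms[[nm]] <- NULL
  left_join(atoms, params[, c("resname", "atom", keep)], by = c("resname", "atom"))
}

#' Read a sidecar nonbonded parameter table
#'
#' Tab-separated table keyed by `resname` and `atom` with per-atom partial
#' charges (e), LJ well depths `eps` (kcal/mol), `rmin2` (rmin/2, Angstrom)
#' and vdW `radius` (Angstrom).
#'
#' @param path TSV file path.
#' @return A tibble.
#' @export
read_param_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Read trajectory frames from a DCD file
#'
#' @param path DCD file path.
#' @param topology The matching `elp_topology`.
#' @param times Frame times in ns (length = number of frames in the file).
#' @param ... Passed to [new_trajectory()].
#' @return An `elp_trajectory`.
#' @export
read_frames_dcd <- function(path, topology, times, ...) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    abort("Package 'bio3d' is required to read DCD files")
  }
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  n_frames <- nrow(xyz)
  n_atoms <- ncol(xyz) / 3
  coords <- array(NA_real_, dim = c(n_frames, n_atoms, 3))
  for (f in seq_len(n_frames)) {
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  }
  new_trajectory(topology, coords, times, ...)
}

#' Read or write trajectory frames as tidy CSV
#'
#' The plain-text fallback format: one row per atom per frame with columns
#' `frame`, `time_ns`, `atom` (1-based index), `x`, `y`, `z`.
#'
#' @param path CSV file path.
#' @param topology The matching `elp_topology`.
#' @param ... Passed to [new_trajectory()].
#' @return `read_frames_csv()` returns an `elp_trajectory`;
#'   `write_frames_csv()` returns `path` invisibly.
#' @export
read_frames_csv <- function(path, topology, ...) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  frames <- sort(unique(df$frame))
  times <- vapply(frames, function(f) df$time_ns[df$frame == f][1], numeric(1))
  n_atoms <- nrow(topology)
  coords <- array(NA_real_, dim = c(length(frames), n_atoms, 3))
  for (i in seq_along(frames)) {
    sub <- df[df$frame == frames[i], ]
    sub <- sub[order(sub$atom), ]
    if (nrow(sub) != n_atoms) abort("Frame atom count does not match topology")
    coords[i, , ] <- as.matrix(sub[, c("x", "y", "z")])
  }
  new_trajectory(topology, coords, times, ...)
}

#' @rdname read_frames_csv
#' @param traj An `elp_trajectory` to write.
#' @export
write_frames_csv <- function(traj, path) {
  n_frames <- dim(traj$coords)[1]
  n_atoms <- dim(traj$coords)[2]
  df <- purrr::map_dfr(seq_len(n_frames), function(f) {
    xyz <- frame_coords(traj, f)
    tibble(
      frame = f, time_ns = traj$times[f], atom = seq_len(n_atoms),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
    )
  })
  readr::write_csv(df, path)
  invisible(path)
}
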
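# S3 containers for backbone structures and trajectory ensembles.
#
# A backbone_structure holds one conformation of a single protein chain at
# N/CA/C resolution; coordinates are in Angstrom and residues keep the
# author numbering of the input file verbatim. A trajectory_ensemble is a
# labeled stack of conformations sharing one atom layout, stored as an
# F x (3 * n_atoms) coordinate matrix in bio3d xyz convention
# (x1, y1, z1, x2, ...), with atoms ordered N, CA, C within each residue.

#' Construct a backbone structure
#'
#' @param residue_ids integer vector, strictly increasing author numbering.
#' @param residue_names character vector of 3-letter residue codes.
#' @param chain_id single chain identifier.
#' @param coords numeric matrix with one row per atom (columns x, y, z),
#'   rows ordered to match `layout`.
#' @param layout data.frame with columns `residue_id` and `atom`
#'   (one of "N", "CA", "C") describing the rows of `coords`. Every residue
#'   must have a CA atom; N and C are optional but required for phi/psi
#'   torsions.
#' @param ss_labels per-residue secondary structure, one of
#'   `"helix"`, `"three_ten"`, `"loop"`; defaults to all-loop.
#'
#' @return An object of class `backbone_structure`.
#' @export
backbone_structure <- function(residue_ids, residue_names, chain_id, coords,
                               layout, ss_labels = NULL) {
  residue_ids <- as.integer(residue_ids)
  n <- length(residue_ids)
  if (n < 1L) stop("structure must contain at least one residue")
  if (any(diff(residue_ids) <= 0L))
    stop("residue_ids must be strictly increasing")
  if (length(residue_names) != n)
    stop("residue_names length does not match residue_ids")
  if (is.null(ss_labels)) ss_labels <- rep("loop", n)
  if (length(ss_labels) != n)
    stop("ss_labels length does not match residue count")
  if (!all(ss_labels %in% c("helix", "three_ten", "loop")))
    stop("ss_labels must be 'helix', 'three_ten' or 'loop'")
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L || nrow(coords) != nrow(layout))
    stop("coords must be an n_atoms x 3 matrix matching the layout")
  if (!all(is.finite(coords))) stop("all coordinates must be finite")
  layout$residue_id <- as.integer(layout$residue_id)
  if (!all(layout$atom %in% c("N", "CA", "C")))
    stop("layout atoms must be N, CA or C")
  if (!all(layout$residue_id %in% residue_ids))
    stop("layout refers to residues absent from residue_ids")
  ca_per_res <- vapply(residue_ids, function(r)
    sum(layout$residue_id == r & layout$atom == "CA"), integer(1))
  if (any(ca_per_res != 1L))
    stop("missing CA atom for residue ",
         residue_ids[which(ca_per_res != 1L)[1]])
  structure(
    list(residue_ids = residue_ids,
         residue_names = as.character(residue_names),
         chain_id = as.character(chain_id),
         coords = unname(coords),
         layout = data.frame(residue_id = layout$residue_id,
                             atom = as.character(layout$atom),
                             stringsAsFactors = FALSE),
         ss_labels = as.character(ss_labels)),
    class = "backbone_structure")
}

#' Construct a trajectory ensemble
#'
#' @param label free-text state name (e.g. `"KIX"`, `"KIX:MLL"`).
#' @param template a [backbone_structure] providing the shared atom layout,
#'   residue numbering and secondary structure of every frame.
#' @param xyz numeric F x (3 * n_atoms) matrix of frame coordinates in the
#'   bio3d xyz column order implied by `template$layout`.
#' @param frame_interval time per frame in ps (informational only).
#' @param equilibration_frame number of leading frames excluded from all
#'   ensemble statistics (0 <= value < F).
#'
#' @return An object of class `trajectory_ensemble`.
#' @export
trajectory_ensemble <- function(label, template, xyz, frame_interval = 1,
                                equilibration_frame = 0L) {
  stopifnot(inherits(template, "backbone_structure"))
  xyz <- as.matrix(xyz)
  n_atoms <- nrow(template$layout)
  if (ncol(xyz) != 3L * n_atoms)
    stop("xyz has ", ncol(xyz), " columns; layout implies ", 3L * n_atoms)
  if (nrow(xyz) < 1L) stop("ensemble must contain at least one frame")
  if (!all(is.finite(xyz))) stop("all frame coordinates must be finite")
  equilibration_frame <- as.integer(equilibration_frame)
  if (equilibration_frame < 0L || equilibration_frame >= nrow(xyz))
    stop("equilibration_frame must satisfy 0 <= value < n_frames")
  structure(
    list(label = as.character(label),
         template = template,
         xyz = unname(xyz),
         frame_interval = frame_interval,
         equilibration_frame = equilibration_frame),
    class = "trajectory_ensemble")
}

#' @export
print.backbone_structure <- function(x, ...) {
  cat("<backbone_structure> chain", x$chain_id, "-",
      length(x$residue_ids), "residues,", nrow(x$layout), "atoms\n")
  cat("  residues", x$residue_ids[1], "..",
      x$residue_ids[length(x$residue_ids)], "\n")
  ss <- table(factor(x$ss_labels, c("helix", "three_ten", "loop")))
  cat("  secondary structure:", paste(names(ss), ss, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat("<trajectory_ensemble>", x$label, "-", nrow(x$xyz), "frames x",
      nrow(x$template$layout), "atoms\n")
  cat("  equilibration_frame:", x$equilibration_frame,
      " frame_interval:", x$frame_interval, "ps\n")
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble a [trajectory_ensemble]
#' @return integer frame count
#' @export
n_frames <- function(ensemble) nrow(ensemble$xyz)

#' Indices of post-equilibration frames
#' @param ensemble a [trajectory_ensemble]
#' @return integer vector of frame indices used by ensemble statistics
#' @export
equilibrated_frames <- function(ensemble) {
  (ensemble$equilibration_frame + 1L):nrow(ensemble$xyz)
}

# xyz column indices (x, y, z triplets) for a set of atom rows
atom_xyz_cols <- function(atom_rows) {
  as.vector(rbind(3L * atom_rows - 2L, 3L * atom_rows - 1L, 3L * atom_rows))
}

# rows of the layout holding CA atoms, optionally restricted to residue ids
ca_rows <- function(obj, residues = NULL) {
  layout <- if (inherits(obj, "trajectory_ensemble")) obj$template$layout
            else obj$layout
  rows <- which(layout$atom == "CA")
  if (!is.null(residues)) {
    keep <- layout$residue_id[rows] %in% residues
    if (!any(keep)) stop("selection matches no residues")
    rows <- rows[keep]
  }
  rows
}

#' Extract CA coordinates
#'
#' @param obj a [backbone_structure] or [trajectory_ensemble]
#' @param residues optional residue-id vector restricting the selection
#' @param frame for ensembles, the frame to extract (default 1)
#' @return numeric n x 3 matrix of CA coordinates (Angstrom)
#' @export
ca_coords <- function(obj, residues = NULL, frame = 1L) {
  rows <- ca_rows(obj, residues)
  if (inherits(obj, "backbone_structure")) {
    obj$coords[rows, , drop = FALSE]
  } else {
    matrix(obj$xyz[frame, atom_xyz_cols(rows)], ncol = 3L, byrow = TRUE)
  }
}

# coordinates of one atom kind for one residue (or NULL if absent)
atom_coord <- function(structure, residue_id, atom) {
  row <- which(structure$layout$residue_id == residue_id &
               structure$layout$atom == atom)
  if (length(row) == 0L) return(NULL)
  structure$coords[row, ]
}

#' Extract one frame of an ensemble as a coordinate matrix
#' @param ensemble a [trajectory_ensemble]
#' @param frame frame index
#' @return n_atoms x 3 numeric matrix (Angstrom)
#' @export
frame_coords <- function(ensemble, frame) {
  matrix(ensemble$xyz[frame, ], ncol = 3L, byrow = TRUE)
}

#' Replace one frame of an ensemble
#' @param ensemble a [trajectory_ensemble]
#' @param frame frame index
#' @param coords n_atoms x 3 coordinate matrix
#' @return the modified ensemble
#' @export
set_frame_coords <- function(ensemble, frame, coords) {
  ensemble$xyz[frame, ] <- as.vector(t(coords))
  ensemble
}

# a backbone_structure from one frame of an ensemble
frame_structure <- function(ensemble, frame) {
  tmpl <- ensemble$template
  tmpl$coords <- frame_coords(ensemble, frame)
  tmpl
}

#' Expand residue-range strings into residue ids
#'
#' Accepts `"START-END"` strings, plain numbers, or vectors/lists of
#' either, and returns the sorted unique residue ids they cover. This is
#' the format regions take in configuration files and on the command
#' line.
#'
#' @param ranges e.g. `"606-628"`, `c("597-611", "623-640")`, or a
#'   numeric vector of ids
#' @return sorted integer vector of residue ids
#' @export
expand_residue_ranges <- function(ranges) {
  if (is.numeric(ranges)) return(as.integer(ranges))
  out <- integer(0)
  for (r in ranges) {
    if (is.numeric(r)) { out <- c(out, as.integer(r)); next }
    m <- regmatches(r, regexec("^\\s*(-?\\d+)\\s*-\\s*(-?\\d+)\\s*$", r))[[1]]
    if (length(m) == 3L) {
      out <- c(out, seq.int(as.integer(m[2]), as.integer(m[3])))
    } else if (grepl("^\\s*-?\\d+\\s*$", r)) {
      out <- c(out, as.integer(r))
    } else {
      stop("cannot parse residue range '", r, "' (expected START-END)")
    }
  }
  sort(unique(out))
}
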
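# Per-frame geometric layer: Kabsch superposition, RMSD/RMSF, average
# structures, equilibration detection from RMSD trends, and backbone /
# CA pseudo torsions. Superposition and RMSD use CA atoms only with
# uniform weights; other atoms are carried along but never weighted.

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the CA RMSD of
#' `mobile` onto `reference` over the given selection. Reflections are
#' excluded, so the result is always a physical rigid motion. Coordinates
#' transform as `x %*% rotation + translation` (row-vector convention).
#'
#' @param mobile,reference n x 3 coordinate matrices (or
#'   [backbone_structure] objects, in which case CA coordinates of the
#'   selected residues are used)
#' @param selection optional residue-id vector (structures) or row index
#'   vector (matrices) restricting the fit
#' @return a list of class `superposition` with elements `rotation`
#'   (3 x 3, det +1), `translation` (length 3, Angstrom) and `rmsd`
#'   (Angstrom, over the selection used)
#' @export
kabsch_superpose <- function(mobile, reference, selection = NULL) {
  P <- as_point_matrix(mobile, selection)
  Q <- as_point_matrix(reference, selection)
  if (nrow(P) != nrow(Q))
    stop("mobile and reference selections have different sizes (",
         nrow(P), " vs ", nrow(Q), ")")
  if (nrow(P) < 3L) stop("superposition needs at least 3 points")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  if (is_collinear(Pc) || is_collinear(Qc))
    stop("degenerate (collinear) selection: superposition is not unique")
  H <- crossprod(Pc, Qc)                 # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  # row-vector convention: transformed = x %*% R + t
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  t_vec <- as.vector(cq - cp %*% R)
  fitted <- Pc %*% R
  rmsd <- sqrt(mean(rowSums((fitted - Qc)^2)))
  structure(list(rotation = R, translation = t_vec, rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat("<superposition> rmsd =", format(x$rmsd, digits = 6), "A\n")
  invisible(x)
}

as_point_matrix <- function(obj, selection = NULL) {
  if (inherits(obj, "backbone_structure")) return(ca_coords(obj, selection))
  m <- as.matrix(obj)
  if (ncol(m) != 3L) stop("coordinate matrix must have 3 columns")
  if (!is.null(selection)) m <- m[selection, , drop = FALSE]
  m
}

is_collinear <- function(centered, tol = 1e-8) {
  s <- svd(centered, nu = 0, nv = 0)$d
  s[2] < tol * max(s[1], 1)
}

#' Apply a superposition to a coordinate matrix
#' @param coords n x 3 coordinate matrix
#' @param sp a `superposition` from [kabsch_superpose]
#' @return the transformed n x 3 matrix
#' @export
apply_superposition <- function(coords, sp) {
  sweep(coords %*% sp$rotation, 2, sp$translation, "+")
}

#' Superpose every frame of an ensemble onto a reference structure
#'
#' Each frame is fitted by [kabsch_superpose] on the CA atoms of the
#' selection; the resulting rigid motion is applied to all atoms of the
#' frame. Label and equilibration index are preserved.
#'
#' @param ensemble a [trajectory_ensemble]
#' @param reference a [backbone_structure] with the same residue layout
#' @param selection residue ids used for the fit (default: all residues)
#' @return the aligned [trajectory_ensemble]
#' @export
align_ensemble <- function(ensemble, reference, selection = NULL) {
  check_same_layout(ensemble$template, reference)
  sel_rows <- ca_rows(reference, selection)
  ref_ca <- reference$coords[sel_rows, , drop = FALSE]
  sel_cols <- atom_xyz_cols(sel_rows)
  for (f in seq_len(n_frames(ensemble))) {
    mob_ca <- matrix(ensemble$xyz[f, sel_cols], ncol = 3L, byrow = TRUE)
    sp <- kabsch_superpose(mob_ca, ref_ca)
    ensemble <- set_frame_coords(
      ensemble, f, apply_superposition(frame_coords(ensemble, f), sp))
  }
  ensemble
}

check_same_layout <- function(a, b) {
  if (!identical(a$residue_ids, b$residue_ids) ||
      !identical(a$layout$atom, b$layout$atom) ||
      !identical(a$layout$residue_id, b$layout$residue_id))
    stop("residue/atom layout mismatch between ensemble and reference")
  invisible(TRUE)
}

#' Per-frame CA RMSD of an ensemble against a reference structure
#'
#' By default every frame is independently superposed onto the reference
#' over the selection (CA atoms, uniform weights) and the minimized RMSD
#' recorded. With `superpose = FALSE` the deviation is measured in the
#' current frame of reference without re-fitting, which is the right
#' metric for ensembles already aligned to a common structure.
#'
#' @inheritParams align_ensemble
#' @param superpose fit each frame onto the reference first (default TRUE)
#' @return numeric vector, one RMSD (Angstrom) per frame
#' @export
rmsd_series <- function(ensemble, reference, selection = NULL,
                        superpose = TRUE) {
  check_same_layout(ensemble$template, reference)
  sel_rows <- ca_rows(reference, selection)
  ref_ca <- reference$coords[sel_rows, , drop = FALSE]
  sel_cols <- atom_xyz_cols(sel_rows)
  vapply(seq_len(n_frames(ensemble)), function(f) {
    mob_ca <- matrix(ensemble$xyz[f, sel_cols], ncol = 3L, byrow = TRUE)
    if (superpose) kabsch_superpose(mob_ca, ref_ca)$rmsd
    else sqrt(mean(rowSums((mob_ca - ref_ca)^2)))
  }, numeric(1))
}

#' Average structure of an ensemble
#'
#' Aligns the post-equilibration frames to the reference over the selection
#' and returns their coordinate-wise mean as a structure. With
#' `iterate = TRUE` the frames are re-aligned to the running average until
#' it moves by less than `tol` CA RMSD (or 50 iterations), which removes
#' the dependence on the initial reference orientation.
#'
#' @inheritParams align_ensemble
#' @param iterate re-align to the running average until convergence
#' @param tol convergence threshold on the movement of the average
#'   structure between iterations (Angstrom CA RMSD)
#' @return a [backbone_structure] holding the mean conformation
#' @export
average_structure <- function(ensemble, reference, selection = NULL,
                              iterate = FALSE, tol = 1e-4) {
  frames <- equilibrated_frames(ensemble)
  if (length(frames) < 1L) stop("no post-equilibration frames")
  aligned <- align_ensemble(ensemble, reference, selection)
  avg <- reference
  avg$coords <- matrix(colMeans(
    aligned$xyz[frames, , drop = FALSE]), ncol = 3L, byrow = TRUE)
  if (iterate) {
    for (i in seq_len(50L)) {
      prev <- avg
      aligned <- align_ensemble(aligned, avg, selection)
      avg$coords <- matrix(colMeans(
        aligned$xyz[frames, , drop = FALSE]), ncol = 3L, byrow = TRUE)
      moved <- kabsch_superpose(ca_coords(avg, selection),
                                ca_coords(prev, selection))$rmsd
      if (moved < tol) break
    }
  }
  avg
}

#' Detect the equilibration point of an RMSD series
#'
#' Scans for the smallest frame index `i` such that over the window
#' `[i, i + window)` the least-squares slope of RMSD against frame number
#' is at most `slope_tol` in magnitude and the standard deviation is at
#' most `sd_tol`. If no window qualifies, the last frame index is returned
#' with attribute `converged = FALSE` and a warning.
#'
#' @param series numeric per-frame RMSD values (Angstrom)
#' @param window window length in frames (>= 2)
#' @param slope_tol maximum |slope| in Angstrom/frame
#' @param sd_tol maximum standard deviation within the window (Angstrom)
#' @return integer index (1-based) of the first equilibrated frame, with
#'   logical attribute `converged`
#' @export
detect_equilibration <- function(series, window, slope_tol = 1e-3,
                                 sd_tol = 0.1) {
  window <- as.integer(window)
  if (window < 2L) stop("window must be at least 2 frames")
  n <- length(series)
  if (n < 2L * window)
    stop("series too short: need at least 2*window = ", 2L * window,
         " frames, got ", n)
  x <- seq_len(window)
  sxx <- sum((x - mean(x))^2)
  xc <- x - mean(x)
  for (i in seq_len(n - window + 1L)) {
    y <- series[i:(i + window - 1L)]
    slope <- sum(xc * (y - mean(y))) / sxx
    if (abs(slope) <= slope_tol && stats::sd(y) <= sd_tol)
      return(structure(i, converged = TRUE))
  }
  warning("no equilibrated window found; returning the last frame")
  structure(n, converged = FALSE)
}

#' Per-residue root-mean-square fluctuation
#'
#' RMSF of each residue's CA about its position in `average`, over the
#' post-equilibration frames of an already-aligned ensemble:
#' `RMSF_i = sqrt(mean_t |r_i(t) - r_i(avg)|^2)`.
#'
#' @param aligned_ensemble a [trajectory_ensemble] already superposed into
#'   a common frame (see [align_ensemble])
#' @param average reference for the deviations, normally the
#'   [average_structure] of the same frames; if omitted, the
#'   post-equilibration mean of the ensemble itself is used
#' @return named numeric vector of per-residue RMSF (Angstrom), names =
#'   residue ids
#' @export
rmsf <- function(aligned_ensemble, average = NULL) {
  frames <- equilibrated_frames(aligned_ensemble)
  if (length(frames) < 2L)
    stop("RMSF needs at least 2 post-equilibration frames")
  rows <- ca_rows(aligned_ensemble)
  cols <- atom_xyz_cols(rows)
  xyz <- aligned_ensemble$xyz[frames, cols, drop = FALSE]
  if (is.null(average)) {
    ref <- colMeans(xyz)
  } else {
    ref <- as.vector(t(ca_coords(average)))
  }
  dev2 <- sweep(xyz, 2, ref)^2
  # sum x,y,z per residue, mean over frames
  per_res <- colMeans(dev2)
  out <- sqrt(per_res[seq(1, length(per_res), 3)] +
              per_res[seq(2, length(per_res), 3)] +
              per_res[seq(3, length(per_res), 3)])
  names(out) <- aligned_ensemble$template$layout$residue_id[rows]
  out
}

# dihedral angle (degrees, IUPAC sign, range (-180, 180]) for stacks of
# four points given as F x 3 matrices
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- row_cross(b1, b2)
  n2 <- row_cross(b2, b3)
  m1 <- row_cross(n1, b2 / sqrt(rowSums(b2^2)))
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  ang <- -atan2(y, x) * 180 / pi
  ang[ang <= -180] <- ang[ang <= -180] + 360
  ang
}

row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Backbone and CA pseudo-torsion series of an ensemble
#'
#' Computes, for every frame, one of the torsion sets:
#' \describe{
#'   \item{phi}{C(i-1)-N(i)-CA(i)-C(i); undefined at the first residue.}
#'   \item{psi}{N(i)-CA(i)-C(i)-N(i+1); undefined at the last residue.}
#'   \item{pseudo_dihedral}{the virtual-bond torsion
#'     CA(i)-CA(i+1)-CA(i+2)-CA(i+3) of the CA trace, labeled by residue i.}
#' }
#' Angles follow the IUPAC sign convention and lie in (-180, 180] degrees.
#'
#' @param ensemble a [trajectory_ensemble] (torsions are invariant to
#'   global rotation/translation, so alignment is not required). A
#'   [backbone_structure] is accepted and treated as a 1-frame ensemble.
#' @param kind one of `"phi"`, `"psi"`, `"pseudo_dihedral"`
#' @return a list of class `angle_series` with `kind`, `torsion_labels`
#'   (residue id defining each torsion) and `values` (F x T matrix,
#'   degrees)
#' @export
torsion_series <- function(ensemble,
                           kind = c("phi", "psi", "pseudo_dihedral")) {
  kind <- match.arg(kind)
  if (inherits(ensemble, "backbone_structure")) {
    tmpl <- ensemble
    xyz <- matrix(as.vector(t(ensemble$coords)), nrow = 1L)
  } else {
    tmpl <- ensemble$template
    xyz <- ensemble$xyz
  }
  layout <- tmpl$layout
  rid <- tmpl$residue_ids
  n <- length(rid)
  atom_row <- function(r, a) {
    i <- which(layout$residue_id == r & layout$atom == a)
    if (length(i) == 0L) NA_integer_ else i
  }
  quads <- list(); labels <- integer(0)
  if (kind == "pseudo_dihedral") {
    if (n < 4L) stop("pseudo-dihedrals need at least 4 residues")
    for (i in seq_len(n - 3L)) {
      quads[[length(quads) + 1L]] <-
        vapply(rid[i:(i + 3L)], atom_row, integer(1), a = "CA")
      labels <- c(labels, rid[i])
    }
  } else if (kind == "phi") {
    for (i in 2:n) {
      quads[[length(quads) + 1L]] <-
        c(atom_row(rid[i - 1L], "C"), atom_row(rid[i], "N"),
          atom_row(rid[i], "CA"), atom_row(rid[i], "C"))
      labels <- c(labels, rid[i])
    }
  } else {
    for (i in seq_len(n - 1L)) {
      quads[[length(quads) + 1L]] <-
        c(atom_row(rid[i], "N"), atom_row(rid[i], "CA"),
          atom_row(rid[i], "C"), atom_row(rid[i + 1L], "N"))
      labels <- c(labels, rid[i])
    }
  }
  missing <- vapply(quads, anyNA, logical(1))
  if (any(missing))
    stop("missing backbone atoms for ", kind, " at residues ",
         paste(labels[missing], collapse = ", "))
  values <- matrix(NA_real_, nrow = nrow(xyz), ncol = length(quads))
  for (j in seq_along(quads)) {
    q <- quads[[j]]
    p <- lapply(q, function(r)
      xyz[, (3L * r - 2L):(3L * r), drop = FALSE])
    values[, j] <- dihedral_angle(p[[1]], p[[2]], p[[3]], p[[4]])
  }
  structure(list(kind = kind, torsion_labels = labels, values = values),
            class = "angle_series")
}

#' @export
print.angle_series <- function(x, ...) {
  cat("<angle_series>", x$kind, "-", nrow(x$values), "frames x",
      ncol(x$values), "torsions\n")
  invisible(x)
}
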
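# Normalized cross-correlation maps of residue fluctuations.
#
# Cartesian maps: C_ij = <dRi . dRj> / sqrt(<|dRi|^2><|dRj|^2>) with dRi
# the deviation of residue i's CA position from its post-equilibration
# mean, frames having been aligned to the minimized/reference structure
# beforehand. Angular maps apply the same normalized form to torsion
# fluctuations after unwrapping each angle trajectory around its circular
# mean, so that crossings of the +-180 degree seam do not create spurious
# decorrelation. Both give symmetric unit-diagonal matrices in [-1, 1].

new_correlation_map <- function(matrix, labels, kind, ensemble_label,
                                n_frames) {
  m <- as.matrix(matrix)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m[m > 1] <- 1
  m[m < -1] <- -1
  out <- structure(list(kind = kind, labels = as.integer(labels),
                        matrix = unname(m), n_frames = n_frames,
                        ensemble_label = ensemble_label),
                   class = "correlation_map")
  assert_correlation_map(out)
  out
}

# structural contract, asserted on every construction
assert_correlation_map <- function(map, tol = 1e-12) {
  m <- map$matrix
  stopifnot(nrow(m) == ncol(m), nrow(m) == length(map$labels))
  if (max(abs(m - t(m))) > tol) stop("correlation map is not symmetric")
  if (max(abs(diag(m) - 1)) > tol) stop("correlation map diagonal is not 1")
  if (any(m > 1 + tol) || any(m < -1 - tol))
    stop("correlation map entries outside [-1, 1]")
  invisible(map)
}

#' @export
print.correlation_map <- function(x, ...) {
  cat("<correlation_map>", x$kind, "-", nrow(x$matrix), "x", ncol(x$matrix),
      "(", x$ensemble_label, ",", x$n_frames, "frames )\n")
  invisible(x)
}

#' Cartesian fluctuation cross-correlation map (DCCM)
#'
#' Computes the normalized covariance of CA positional fluctuations over
#' the post-equilibration frames of an ensemble aligned to a common
#' reference. By default the fluctuation of residue i is taken about its
#' trajectory mean, which makes the map a true correlation matrix; set
#' `center = "reference"` to measure deviations from the reference
#' structure's coordinates instead (the normalization then uses raw second
#' moments, preserving symmetry and the unit diagonal).
#'
#' @param aligned_ensemble a [trajectory_ensemble] previously superposed
#'   onto the reference (see [align_ensemble])
#' @param center `"mean"` (default) or `"reference"`
#' @param reference required when `center = "reference"`
#' @return a `correlation_map` of kind `"cartesian"`, labeled by residue id
#' @export
cartesian_cross_correlation <- function(aligned_ensemble,
                                        center = c("mean", "reference"),
                                        reference = NULL) {
  center <- match.arg(center)
  frames <- equilibrated_frames(aligned_ensemble)
  if (length(frames) < 2L)
    stop("correlation needs at least 2 post-equilibration frames")
  rows <- ca_rows(aligned_ensemble)
  labels <- aligned_ensemble$template$layout$residue_id[rows]
  xyz <- aligned_ensemble$xyz[frames, atom_xyz_cols(rows), drop = FALSE]
  if (center == "mean") {
    ref <- colMeans(xyz)
  } else {
    if (is.null(reference))
      stop("center = 'reference' requires the reference structure")
    ref <- as.vector(t(ca_coords(reference)))
  }
  d <- sweep(xyz, 2, ref)
  n <- length(labels)
  ix <- seq(1, 3 * n, 3)
  X <- d[, ix, drop = FALSE]
  Y <- d[, ix + 1, drop = FALSE]
  Z <- d[, ix + 2, drop = FALSE]
  cov <- (crossprod(X) + crossprod(Y) + crossprod(Z)) / length(frames)
  v <- diag(cov)
  if (any(v < 1e-12))
    stop("zero fluctuation variance for residue ",
         labels[which(v < 1e-12)[1]], ": correlation undefined")
  C <- cov / sqrt(outer(v, v))
  new_correlation_map(C, labels, "cartesian",
                      aligned_ensemble$label, length(frames))
}

# map angles (degrees) into (mean - 180, mean + 180] around a center
unwrap_about <- function(angles, center) {
  center + ((angles - center + 180) %% 360) - 180
}

circular_mean_deg <- function(angles) {
  atan2(mean(sin(angles * pi / 180)), mean(cos(angles * pi / 180))) * 180 / pi
}

#' Angular fluctuation cross-correlation map
#'
#' Normalized cross-correlation of torsion-angle fluctuations. Each
#' torsion trajectory is first unwrapped: angles are mapped to the
#' representative within 180 degrees of the torsion's circular mean, after
#' which fluctuations are linear deviations from that circular mean. This
#' keeps the linear-correlation form while removing artifacts at the
#' +-180 degree seam. Set `unwrap = FALSE` to correlate raw angles
#' (deviations from the arithmetic mean) instead.
#'
#' @param series an `angle_series` from [torsion_series]
#' @param equilibration_frame leading frames to exclude (default 0; pass
#'   the ensemble's value when the series spans the full trajectory)
#' @param unwrap unwrap each torsion around its circular mean (default)
#' @param ensemble_label label recorded on the map
#' @return a `correlation_map` of the series' kind, labeled by the residue
#'   id defining each torsion
#' @export
angular_cross_correlation <- function(series, equilibration_frame = 0L,
                                      unwrap = TRUE,
                                      ensemble_label = "") {
  stopifnot(inherits(series, "angle_series"))
  vals <- series$values
  if (equilibration_frame > 0L)
    vals <- vals[-seq_len(equilibration_frame), , drop = FALSE]
  if (nrow(vals) < 2L)
    stop("correlation needs at least 2 post-equilibration frames")
  if (unwrap) {
    d <- vals
    for (j in seq_len(ncol(vals))) {
      mu <- circular_mean_deg(vals[, j])
      d[, j] <- unwrap_about(vals[, j], mu) - mu
    }
  } else {
    d <- sweep(vals, 2, colMeans(vals))
  }
  second <- crossprod(d) / nrow(d)
  v <- diag(second)
  if (any(v < 1e-12))
    stop("zero fluctuation variance for torsion at residue ",
         series$torsion_labels[which(v < 1e-12)[1]])
  C <- second / sqrt(outer(v, v))
  new_correlation_map(C, series$torsion_labels, series$kind,
                      ensemble_label, nrow(d))
}

#' Mean correlation between two residue regions
#'
#' Summarizes the coupling between two disjoint residue ranges of a
#' correlation map as the mean (and mean absolute) map entry over all
#' cross pairs, the quantitative analogue of reading inter-region blocks
#' off a plotted map.
#'
#' @param map a `correlation_map`
#' @param region_a,region_b residue-id vectors or `"START-END"` strings;
#'   must be disjoint and map to at least one label each
#' @return a list of class `region_coupling` with `score`, `abs_score`,
#'   `n_pairs`, the regions, and the map's kind and ensemble label
#' @export
region_coupling <- function(map, region_a, region_b) {
  stopifnot(inherits(map, "correlation_map"))
  a <- expand_residue_ranges(region_a)
  b <- expand_residue_ranges(region_b)
  if (length(intersect(a, b)) > 0L)
    stop("regions must be disjoint")
  ia <- which(map$labels %in% a)
  ib <- which(map$labels %in% b)
  if (length(ia) == 0L || length(ib) == 0L)
    stop("a region matches no labels of the map")
  block <- map$matrix[ia, ib, drop = FALSE]
  structure(list(score = mean(block), abs_score = mean(abs(block)),
                 n_pairs = length(block),
                 region_a = a, region_b = b,
                 kind = map$kind, ensemble_label = map$ensemble_label),
            class = "region_coupling")
}

#' @export
print.region_coupling <- function(x, ...) {
  cat("<region_coupling>", x$kind, "(", x$ensemble_label, ")",
      sprintf("score = %.4f, |score| = %.4f over %d pairs\n",
              x$score, x$abs_score, x$n_pairs))
  invisible(x)
}

#' Entrywise difference of two correlation maps
#'
#' Supports wild-type vs mutant contrasts: returns `map_a - map_b` as a
#' [matrix_record]. The two maps must share kind and labels; the result is
#' antisymmetric under argument swap.
#'
#' @param map_a,map_b `correlation_map` objects of the same kind and labels
#' @return a [matrix_record] of kind `"difference"`
#' @export
difference_map <- function(map_a, map_b) {
  stopifnot(inherits(map_a, "correlation_map"),
            inherits(map_b, "correlation_map"))
  if (!identical(map_a$kind, map_b$kind))
    stop("cannot difference maps of kinds '", map_a$kind, "' and '",
         map_b$kind, "'")
  if (!identical(map_a$labels, map_b$labels))
    stop("maps have different torsion/residue labels")
  matrix_record(map_a$matrix - map_b$matrix,
                row_labels = map_a$labels, col_labels = map_a$labels,
                kind = "difference",
                metadata = list(
                  map_kind = map_a$kind,
                  ensemble_a = map_a$ensemble_label,
                  ensemble_b = map_b$ensemble_label))
}

#' Convert a correlation map to a matrix record for writing
#' @param map a `correlation_map`
#' @return a [matrix_record] carrying kind, ensemble label and frame count
#' @export
as_matrix_record <- function(map) {
  stopifnot(inherits(map, "correlation_map"))
  matrix_record(map$matrix, map$labels, map$labels, kind = map$kind,
                metadata = list(ensemble = map$ensemble_label,
                                n_frames = map$n_frames))
}

#' Heatmap of a correlation map
#'
#' Base-graphics image of the map on a blue-white-red scale with residue
#' ids on the axes.
#'
#' @param x a `correlation_map`
#' @param ... passed to [graphics::image]
#' @export
plot.correlation_map <- function(x, ...) {
  n <- length(x$labels)
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(101)
  graphics::image(seq_len(n), seq_len(n), x$matrix, zlim = c(-1, 1),
                  col = pal, xlab = "residue", ylab = "residue",
                  axes = FALSE,
                  main = paste0(x$kind, " correlations (", x$ensemble_label,
                                ")"), ...)
  at <- pretty(seq_len(n))
  at <- at[at >= 1 & at <= n]
  graphics::axis(1, at = at, labels = x$labels[at])
  graphics::axis(2, at = at, labels = x$labels[at])
  graphics::box()
  invisible(x)
}
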
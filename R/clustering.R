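# Radius-bounded k-means clustering of merged labeled conformational
# ensembles (kclust-style fixed-radius semantics) and quantification of
# per-state population overlap.
#
# Frames are assumed pre-aligned to a common average structure, so the CA
# RMSD between two conformations over the selection reduces to a Euclidean
# distance in flattened coordinate space divided by sqrt(n_sel). k is
# grown from 1, with deterministic farthest-point seeding from the given
# seed, until every frame lies within the radius of its own center; Lloyd
# iterations refine centers to assignment convergence. Ties in assignment
# go to the lowest cluster id; an emptied cluster keeps its center. This
# makes the whole procedure bit-reproducible given (input, seed).

# run a function with a temporary RNG state derived from seed
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

# merged post-equilibration frame matrix over the selection CA atoms
merged_frame_matrix <- function(ensembles, selection = NULL) {
  stopifnot(length(ensembles) >= 1L)
  ref_layout <- ensembles[[1]]$template
  for (e in ensembles) check_same_layout(e$template, ref_layout)
  rows <- ca_rows(ref_layout, selection)
  cols <- atom_xyz_cols(rows)
  blocks <- lapply(ensembles, function(e)
    e$xyz[equilibrated_frames(e), cols, drop = FALSE])
  X <- do.call(rbind, blocks)
  labels <- unlist(lapply(ensembles, function(e)
    rep(e$label, length(equilibrated_frames(e)))))
  frame_idx <- unlist(lapply(ensembles, equilibrated_frames))
  list(X = X, labels = labels, frame_idx = frame_idx,
       n_sel = length(rows),
       selection_ids = ref_layout$layout$residue_id[rows])
}

# squared Euclidean distances between rows of X and rows of C
cross_dist2 <- function(X, C) {
  d2 <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * tcrossprod(X, C)
  d2[d2 < 0] <- 0
  d2
}

# deterministic farthest-point seeding sequence of length k_max
farthest_point_sequence <- function(X, k_max, seed) {
  n <- nrow(X)
  first <- with_seed(seed, sample.int(n, 1L))
  idx <- integer(k_max)
  idx[1] <- first
  if (k_max == 1L) return(idx)
  d2 <- cross_dist2(X, X[first, , drop = FALSE])[, 1]
  for (k in 2:k_max) {
    idx[k] <- which.max(d2)        # lowest index on ties
    d2 <- pmin(d2, cross_dist2(X, X[idx[k], , drop = FALSE])[, 1])
  }
  idx
}

# Lloyd iterations with lowest-id tie-break; empty clusters keep centers
lloyd_kmeans <- function(X, centers, max_iter = 200L) {
  assign_prev <- rep(0L, nrow(X))
  for (it in seq_len(max_iter)) {
    d2 <- cross_dist2(X, centers)
    assign <- max.col(-d2, ties.method = "first")
    if (identical(assign, assign_prev)) break
    assign_prev <- assign
    for (c in seq_len(nrow(centers))) {
      members <- which(assign == c)
      if (length(members) > 0L)
        centers[c, ] <- colMeans(X[members, , drop = FALSE])
    }
  }
  d2 <- cross_dist2(X, centers)
  assign <- max.col(-d2, ties.method = "first")
  list(assign = assign,
       centers = centers,
       dist = sqrt(d2[cbind(seq_len(nrow(X)), assign)]))
}

# shared driver: cluster merged frames growing k until max RMSD <= radius
grow_clusters <- function(X, radius, n_sel, seed, max_iter = 200L) {
  n <- nrow(X)
  seq_idx <- NULL
  for (k in seq_len(n)) {
    if (is.null(seq_idx) || k > length(seq_idx))
      seq_idx <- farthest_point_sequence(X, min(n, max(k, 8L)), seed)
    fit <- lloyd_kmeans(X, X[seq_idx[seq_len(k)], , drop = FALSE], max_iter)
    max_rmsd <- max(fit$dist) / sqrt(n_sel)
    if (max_rmsd <= radius)
      return(list(k = k, fit = fit, max_rmsd = max_rmsd))
  }
  stop("radius ", radius, " A is too small for ", n,
       " frames; increase the radius")
}

#' Radius-bounded combinatorial clustering of labeled ensembles
#'
#' Pools the post-equilibration frames of all ensembles (which must share
#' one residue layout and be pre-aligned to a common average structure)
#' and k-means-clusters them in CA coordinate space over the selection,
#' growing k from 1 until the maximum frame-to-own-center RMSD does not
#' exceed `radius`.
#'
#' @param ensembles list of [trajectory_ensemble] objects with unique labels
#' @param radius cluster radius threshold in Angstrom (> 0)
#' @param selection residue ids used for the RMSD metric (default: all)
#' @param seed integer seed making the farthest-point initialization (and
#'   hence the whole procedure) reproducible
#' @return a list of class `cluster_model`: `radius_threshold`,
#'   `selection` (residue ids used), `centers` (k x (3 n_sel) matrix),
#'   `assignments` (data.frame label / frame / cluster / rmsd_to_center),
#'   `k`, `occupancy` (label x cluster count table), `max_rmsd`
#' @export
combinatorial_cluster <- function(ensembles, radius, selection = NULL,
                                  seed = 1L) {
  if (radius <= 0) stop("radius must be positive")
  labels <- vapply(ensembles, function(e) e$label, character(1))
  if (anyDuplicated(labels))
    stop("ensemble labels must be unique: ",
         labels[anyDuplicated(labels)])
  m <- merged_frame_matrix(ensembles, selection)
  res <- grow_clusters(m$X, radius, m$n_sel, seed)
  rmsd_to_center <- res$fit$dist / sqrt(m$n_sel)
  if (max(rmsd_to_center) > radius + 1e-9)
    stop("internal error: radius bound violated after clustering")
  assignments <- data.frame(label = m$labels, frame = m$frame_idx,
                            cluster = res$fit$assign,
                            rmsd_to_center = rmsd_to_center,
                            stringsAsFactors = FALSE)
  occupancy <- table(factor(m$labels, unique(labels)),
                     factor(res$fit$assign, seq_len(res$k)))
  names(dimnames(occupancy)) <- c("label", "cluster")
  structure(list(radius_threshold = radius,
                 selection = m$selection_ids,
                 centers = res$fit$centers,
                 assignments = assignments,
                 k = res$k,
                 occupancy = occupancy,
                 max_rmsd = res$max_rmsd,
                 seed = seed),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("<cluster_model> k =", x$k, "at radius", x$radius_threshold,
      "A (max member RMSD", format(x$max_rmsd, digits = 4), "A)\n")
  print(x$occupancy)
  invisible(x)
}

#' Cluster-count sweep over radius thresholds
#'
#' Runs the radius-bounded clustering once per threshold on identical
#' merged input. Per-k clusterings are shared across thresholds (same
#' deterministic seeding), so the returned k is non-increasing in the
#' radius by construction.
#'
#' @inheritParams combinatorial_cluster
#' @param radii numeric vector of radius thresholds (Angstrom)
#' @return data.frame with columns `radius` and `k`
#' @export
sweep_radius <- function(ensembles, radii, selection = NULL, seed = 1L) {
  if (any(radii <= 0)) stop("all radii must be positive")
  m <- merged_frame_matrix(ensembles, selection)
  r_min <- min(radii)
  max_rmsd_k <- numeric(0)
  # evaluate max member RMSD for k = 1, 2, ... until the finest radius holds
  seq_idx <- farthest_point_sequence(m$X, min(nrow(m$X), 8L), seed)
  k <- 0L
  repeat {
    k <- k + 1L
    if (k > nrow(m$X))
      stop("radius ", r_min, " A is too small for ", nrow(m$X), " frames")
    if (k > length(seq_idx))
      seq_idx <- farthest_point_sequence(m$X, min(nrow(m$X), 2L * k), seed)
    fit <- lloyd_kmeans(m$X, m$X[seq_idx[seq_len(k)], , drop = FALSE])
    max_rmsd_k[k] <- max(fit$dist) / sqrt(m$n_sel)
    if (max_rmsd_k[k] <= r_min) break
  }
  k_of <- vapply(radii, function(r) min(which(max_rmsd_k <= r)), integer(1))
  data.frame(radius = radii, k = k_of)
}

#' Ensemble-overlap report from a cluster model
#'
#' Quantifies the population shift between states: a cluster "belongs to"
#' reference ensemble R if R's share of that cluster's members reaches
#' `share_threshold` (default: any nonzero share), and the overlap of
#' query Q with reference R is the percentage of Q's frames assigned to
#' clusters belonging to R.
#'
#' @param model a `cluster_model` from [combinatorial_cluster]
#' @param share_threshold minimum composition fraction for membership;
#'   the default 0 counts any reference presence
#' @return a list of class `overlap_report`: `overlap` (query x reference
#'   percentage matrix, diagonal 100), `composition` (label x cluster
#'   fraction of each cluster's members), `share_threshold`
#' @export
overlap_report <- function(model, share_threshold = 0) {
  stopifnot(inherits(model, "cluster_model"))
  occ <- unclass(model$occupancy)
  labs <- rownames(occ)
  cluster_sizes <- colSums(occ)
  composition <- sweep(occ, 2, pmax(cluster_sizes, 1L), "/")
  overlap <- matrix(NA_real_, length(labs), length(labs),
                    dimnames = list(query = labs, reference = labs))
  for (r in seq_along(labs)) {
    share <- composition[r, ]
    belongs <- if (share_threshold <= 0) share > 0
               else share >= share_threshold
    for (q in seq_along(labs)) {
      total_q <- sum(occ[q, ])
      overlap[q, r] <- if (total_q == 0) NA_real_
                       else 100 * sum(occ[q, belongs]) / total_q
    }
  }
  structure(list(overlap = overlap, composition = composition,
                 share_threshold = share_threshold,
                 radius_threshold = model$radius_threshold,
                 k = model$k),
            class = "overlap_report")
}

#' Overlap percentage between two labeled states
#' @param report an `overlap_report`
#' @param query,reference ensemble labels
#' @return percentage of query frames in clusters occupied by the reference
#' @export
overlap_between <- function(report, query, reference) {
  stopifnot(inherits(report, "overlap_report"))
  for (l in c(query, reference))
    if (!l %in% rownames(report$overlap))
      stop("unknown ensemble label: ", l)
  report$overlap[query, reference]
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("<overlap_report> k =", x$k, "clusters at radius",
      x$radius_threshold, "A, share threshold", x$share_threshold, "\n")
  cat("overlap %% (rows = query, cols = reference):\n")
  print(round(x$overlap, 1))
  invisible(x)
}
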
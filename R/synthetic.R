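# Synthetic KIX-like structures and conformational ensembles with
# analytically known statistics, standing in for undeposited MD
# trajectories.
#
# Three generators are provided: (1) an ideal-geometry backbone builder
# producing N/CA/C chains from per-segment phi/psi values; (2) a Gaussian
# network model (GNM) whose Kirchhoff pseudo-inverse gives the exact
# Cartesian fluctuation correlations an ensemble sampled from it must
# recover; (3) a discrete conformer mixture with prescribed per-state
# population weights, emulating population-shift scenarios. All are
# bit-reproducible given (spec, seed).

# standard trans-peptide internal coordinates (Angstrom / degrees)
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N <- 1.329
ANGLE_N_CA_C <- 111.2
ANGLE_CA_C_N <- 116.2
ANGLE_C_N_CA <- 121.7

SS_TORSIONS <- list(helix = c(phi = -57, psi = -47),
                    three_ten = c(phi = -49, psi = -26))

# small rotamer set for coil residues, sampled reproducibly
COIL_TORSIONS <- matrix(c(-139, 135,
                          -120, 113,
                          -75, 145,
                          -60, 140,
                          -100, 130,
                          -70, -30,
                          -85, 75), ncol = 2, byrow = TRUE,
                        dimnames = list(NULL, c("phi", "psi")))

#' Chain topology specification for the synthetic builder
#'
#' Describes a single chain as an ordered set of secondary-structure
#' segments in author residue numbering; residues not covered by any
#' segment are loop. The default offset 586 echoes the numbering of the
#' KIX domain of CBP.
#'
#' @param n_residues chain length
#' @param segments list of `list(from, to, ss)` entries with `ss` one of
#'   `"helix"`, `"three_ten"`, `"loop"`; ranges use author numbering,
#'   must lie within the chain and must not overlap
#' @param offset residue id of the first residue (default 586)
#' @return an object of class `topology_spec` with an `ss_labels` vector
#'   covering the whole chain
#' @export
topology_spec <- function(n_residues, segments = list(), offset = 586L) {
  n_residues <- as.integer(n_residues)
  offset <- as.integer(offset)
  ids <- seq.int(offset, offset + n_residues - 1L)
  ss <- rep("loop", n_residues)
  claimed <- rep(FALSE, n_residues)
  for (seg in segments) {
    if (!all(c("from", "to", "ss") %in% names(seg)))
      stop("each segment needs from, to and ss")
    if (!seg$ss %in% c("helix", "three_ten", "loop"))
      stop("unknown secondary structure '", seg$ss, "'")
    pos <- match(seq.int(seg$from, seg$to), ids)
    if (anyNA(pos))
      stop("segment ", seg$from, "-", seg$to, " outside the chain")
    if (any(claimed[pos]))
      stop("segment ", seg$from, "-", seg$to, " overlaps another segment")
    claimed[pos] <- TRUE
    ss[pos] <- seg$ss
  }
  structure(list(n_residues = n_residues, offset = offset,
                 residue_ids = ids, ss_labels = ss, segments = segments),
            class = "topology_spec")
}

#' Canonical KIX-like topology
#'
#' The three-helix-bundle layout of the KIX domain in author numbering:
#' 3(10) helix G1 (591-594), helix alpha1 (597-611), 3(10) helix G2
#' (617-621), helix alpha2 (623-640), helix alpha3 (646-669), loops
#' elsewhere (including the L12 loop between alpha1 and G2). Chain spans
#' residues 586-672.
#'
#' @return a [topology_spec] of 87 residues at offset 586
#' @export
kix_topology <- function() {
  topology_spec(87L, segments = list(
    list(from = 591, to = 594, ss = "three_ten"),
    list(from = 597, to = 611, ss = "helix"),
    list(from = 617, to = 621, ss = "three_ten"),
    list(from = 623, to = 640, ss = "helix"),
    list(from = 646, to = 669, ss = "helix")), offset = 586L)
}

# place atom d from a, b, c with given bond |c-d|, angle b-c-d and
# torsion a-b-c-d (NeRF construction; degrees in)
nerf_place <- function(a, b, c, bond, angle, torsion) {
  th <- angle * pi / 180
  chi <- torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d_local <- bond * c(-cos(th), sin(th) * cos(chi), sin(th) * sin(chi))
  c + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

build_backbone_once <- function(spec, phi, psi) {
  n <- spec$n_residues
  coords <- matrix(NA_real_, nrow = 3L * n, ncol = 3L)
  # residue 1 placed in the xy plane
  coords[1, ] <- c(0, 0, 0)                                   # N
  coords[2, ] <- c(BOND_N_CA, 0, 0)                           # CA
  a <- ANGLE_N_CA_C * pi / 180
  coords[3, ] <- coords[2, ] + BOND_CA_C * c(-cos(a), sin(a), 0)  # C
  for (i in seq_len(n - 1L) + 1L) {
    pN <- coords[3L * (i - 2L) + 1L, ]
    pCA <- coords[3L * (i - 2L) + 2L, ]
    pC <- coords[3L * (i - 2L) + 3L, ]
    qN <- nerf_place(pN, pCA, pC, BOND_C_N, ANGLE_CA_C_N, psi[i - 1L])
    qCA <- nerf_place(pCA, pC, qN, BOND_N_CA, ANGLE_C_N_CA, 180)
    qC <- nerf_place(pC, qN, qCA, BOND_CA_C, ANGLE_N_CA_C, phi[i])
    coords[3L * (i - 1L) + 1L, ] <- qN
    coords[3L * (i - 1L) + 2L, ] <- qCA
    coords[3L * (i - 1L) + 3L, ] <- qC
  }
  coords
}

#' Build an ideal-geometry backbone from a topology specification
#'
#' Constructs a full N/CA/C backbone segment by segment from ideal
#' internal coordinates: helices use phi = -57, psi = -47; 3(10) helices
#' phi = -49, psi = -26; loop residues draw phi/psi reproducibly from a
#' small coil set. Peptide bonds are trans (omega = 180) with standard
#' bond lengths and angles. A self-clash check requires every CA-CA pair
#' to be at least 2.5 Angstrom apart; on failure the loop torsions are
#' re-drawn (up to 10 attempts) before giving up.
#'
#' @param spec a [topology_spec]
#' @param seed integer seed for the coil torsion draws
#' @return a [backbone_structure] (residue names ALA, chain A) carrying
#'   the spec's secondary-structure labels
#' @export
build_backbone <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "topology_spec"))
  n <- spec$n_residues
  for (attempt in seq_len(10L)) {
    phi <- numeric(n); psi <- numeric(n)
    loop_idx <- which(spec$ss_labels == "loop")
    draw <- if (length(loop_idx) > 0L)
      with_seed(seed + attempt - 1L,
                sample.int(nrow(COIL_TORSIONS), length(loop_idx),
                           replace = TRUE))
    else integer(0)
    for (i in seq_len(n)) {
      ss <- spec$ss_labels[i]
      if (ss %in% names(SS_TORSIONS)) {
        phi[i] <- SS_TORSIONS[[ss]]["phi"]
        psi[i] <- SS_TORSIONS[[ss]]["psi"]
      } else {
        j <- draw[match(i, loop_idx)]
        phi[i] <- COIL_TORSIONS[j, "phi"]
        psi[i] <- COIL_TORSIONS[j, "psi"]
      }
    }
    coords <- build_backbone_once(spec, phi, psi)
    ca <- coords[seq(2L, 3L * n, 3L), , drop = FALSE]
    dmin <- min(stats::dist(ca))
    if (dmin >= 2.5) {
      layout <- data.frame(
        residue_id = rep(spec$residue_ids, each = 3L),
        atom = rep(c("N", "CA", "C"), n),
        stringsAsFactors = FALSE)
      return(backbone_structure(
        residue_ids = spec$residue_ids,
        residue_names = rep("ALA", n),
        chain_id = "A", coords = coords, layout = layout,
        ss_labels = spec$ss_labels))
    }
  }
  stop("self-clash check failed after 10 attempts; ",
       "the topology's loops cannot be built clash-free")
}

#' Build a Gaussian network model from a structure
#'
#' The Kirchhoff (connectivity) matrix has Gamma_ij = -1 for CA pairs
#' within the distance cutoff, and node degree on the diagonal. Its
#' pseudo-inverse (eigendecomposition with the single zero mode removed)
#' defines the model's analytic fluctuation covariances; the normalized
#' form `Gamma+_ij / sqrt(Gamma+_ii Gamma+_jj)` is the correlation map an
#' infinitely long isotropic sample must reproduce.
#'
#' @param structure a [backbone_structure] (CA atoms define the nodes)
#' @param cutoff contact cutoff in Angstrom (default 7.0, common GNM
#'   practice)
#' @return a list of class `gnm_model`: `kirchhoff`, `pinv`, `cutoff`,
#'   `residue_ids`, and the eigen-decomposition used for sampling
#' @export
gnm_build <- function(structure, cutoff = 7.0) {
  stopifnot(inherits(structure, "backbone_structure"))
  ca <- ca_coords(structure)
  n <- nrow(ca)
  if (n < 4L) stop("GNM needs at least 4 residues")
  d <- as.matrix(stats::dist(ca))
  G <- -(d <= cutoff) * 1
  diag(G) <- 0
  diag(G) <- -rowSums(G)
  finalize_gnm(G, cutoff, structure$residue_ids)
}

finalize_gnm <- function(G, cutoff, residue_ids) {
  eig <- eigen(G, symmetric = TRUE)
  tol <- 1e-8 * max(abs(eig$values), 1)
  zero <- which(abs(eig$values) < tol)
  if (length(zero) > 1L)
    stop("contact graph is disconnected (", length(zero),
         " zero modes); increase the cutoff or restore contacts")
  keep <- setdiff(seq_along(eig$values), zero)
  pinv <- eig$vectors[, keep, drop = FALSE] %*%
    (t(eig$vectors[, keep, drop = FALSE]) / eig$values[keep])
  pinv <- (pinv + t(pinv)) / 2
  structure(list(kirchhoff = G, pinv = pinv, cutoff = cutoff,
                 residue_ids = as.integer(residue_ids),
                 mode_values = eig$values[keep],
                 mode_vectors = eig$vectors[, keep, drop = FALSE]),
            class = "gnm_model")
}

#' @export
print.gnm_model <- function(x, ...) {
  cat("<gnm_model>", length(x$residue_ids), "nodes, cutoff", x$cutoff,
      "A,", sum(x$kirchhoff[upper.tri(x$kirchhoff)] != 0), "contacts\n")
  invisible(x)
}

#' Analytic correlation map of a GNM
#' @param model a `gnm_model`
#' @return a `correlation_map` of kind `"cartesian"` holding
#'   `Gamma+_ij / sqrt(Gamma+_ii Gamma+_jj)`
#' @export
gnm_correlation <- function(model) {
  stopifnot(inherits(model, "gnm_model"))
  v <- diag(model$pinv)
  new_correlation_map(model$pinv / sqrt(outer(v, v)), model$residue_ids,
                      "cartesian", "gnm_analytic", NA_integer_)
}

#' Contact pairs of a GNM
#' @param model a `gnm_model`
#' @param region_a,region_b optional residue-id vectors (or `"START-END"`
#'   strings) restricting the list to contacts bridging two regions
#' @return two-column matrix of residue-id pairs currently connected
#' @export
gnm_contacts <- function(model, region_a = NULL, region_b = NULL) {
  idx <- which(model$kirchhoff != 0 & upper.tri(model$kirchhoff),
               arr.ind = TRUE)
  pairs <- cbind(model$residue_ids[idx[, 1]], model$residue_ids[idx[, 2]])
  if (!is.null(region_a)) {
    a <- expand_residue_ranges(region_a)
    b <- expand_residue_ranges(region_b)
    keep <- (pairs[, 1] %in% a & pairs[, 2] %in% b) |
            (pairs[, 1] %in% b & pairs[, 2] %in% a)
    pairs <- pairs[keep, , drop = FALSE]
  }
  pairs
}

#' Remove contacts from a GNM
#'
#' Zeroes the Kirchhoff entries of the listed residue pairs, re-balances
#' the diagonal and recomputes the pseudo-inverse. Used as a stand-in for
#' coupling-weakening mutations: deleting the springs that bridge two
#' regions strictly weakens their analytic fluctuation correlation.
#'
#' @param model a `gnm_model`
#' @param removed_pairs two-column matrix (or list of length-2 vectors)
#'   of residue-id pairs; every pair must be a current contact
#' @return a new `gnm_model` without those springs
#' @export
perturb_contacts <- function(model, removed_pairs) {
  stopifnot(inherits(model, "gnm_model"))
  if (is.list(removed_pairs))
    removed_pairs <- do.call(rbind, removed_pairs)
  removed_pairs <- matrix(as.integer(removed_pairs), ncol = 2L)
  if (nrow(removed_pairs) == 0L) return(model)
  G <- model$kirchhoff
  for (p in seq_len(nrow(removed_pairs))) {
    i <- match(removed_pairs[p, 1], model$residue_ids)
    j <- match(removed_pairs[p, 2], model$residue_ids)
    if (is.na(i) || is.na(j))
      stop("pair ", removed_pairs[p, 1], "-", removed_pairs[p, 2],
           " names residues outside the model")
    if (G[i, j] == 0)
      stop("pair ", removed_pairs[p, 1], "-", removed_pairs[p, 2],
           " is not a current contact")
    G[i, j] <- 0; G[j, i] <- 0
  }
  diag(G) <- 0
  diag(G) <- -rowSums(G)
  finalize_gnm(G, model$cutoff, model$residue_ids)
}

#' Add springs to a GNM
#'
#' Inserts unit springs between the listed residue pairs (Kirchhoff
#' entries set to -1, diagonal re-balanced) and recomputes the
#' pseudo-inverse. Together with [perturb_contacts] this supports planted
#' coupling experiments: a wild-type-like model carries explicit bridge
#' springs between two regions and the mutant model lacks them.
#'
#' @param model a `gnm_model`
#' @param pairs two-column matrix (or list of length-2 vectors) of
#'   residue-id pairs; pairs already in contact are an error
#' @return a new `gnm_model` with the springs added
#' @export
gnm_add_contacts <- function(model, pairs) {
  stopifnot(inherits(model, "gnm_model"))
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (nrow(pairs) == 0L) return(model)
  G <- model$kirchhoff
  for (p in seq_len(nrow(pairs))) {
    i <- match(pairs[p, 1], model$residue_ids)
    j <- match(pairs[p, 2], model$residue_ids)
    if (is.na(i) || is.na(j))
      stop("pair ", pairs[p, 1], "-", pairs[p, 2],
           " names residues outside the model")
    if (G[i, j] != 0)
      stop("pair ", pairs[p, 1], "-", pairs[p, 2], " is already a contact")
    G[i, j] <- -1; G[j, i] <- -1
  }
  diag(G) <- 0
  diag(G) <- -rowSums(G)
  finalize_gnm(G, model$cutoff, model$residue_ids)
}

#' Wild-type-like and coupling-removed KIX network models
#'
#' Builds the canonical KIX-like backbone, derives its distance-cutoff
#' GNM, and plants an allosteric coupling: bridge springs connecting the
#' L12/G2 loop region (606-628) with the alpha3 region (651-666). The
#' ideal-geometry builder produces the correct secondary structure but
#' not the folded three-helix tertiary arrangement, so these tertiary
#' contacts are planted explicitly. The "mutant" model is the same
#' network with the bridge springs removed, a stand-in for
#' coupling-weakening point mutations in the loop: the analytic (and any
#' sampled) correlation between the two regions is strictly weaker
#' without the bridges.
#'
#' @param seed seed for the backbone build
#' @param cutoff GNM distance cutoff in Angstrom
#' @return list with `structure`, `wt` and `mutant` (`gnm_model`s),
#'   `bridge_pairs`, and the two region definitions `loop_region`,
#'   `alpha3_region`
#' @export
kix_allosteric_models <- function(seed = 1L, cutoff = 7.0) {
  s <- build_backbone(kix_topology(), seed = seed)
  base <- gnm_build(s, cutoff)
  loop_anchor <- c(606, 612, 617, 621, 628)
  a3_anchor <- c(651, 655, 658, 662, 666)
  bridge <- as.matrix(expand.grid(loop_anchor, a3_anchor))
  colnames(bridge) <- NULL
  # a loop conformation may already place a pair in distance contact;
  # plant only the springs that are missing
  existing <- vapply(seq_len(nrow(bridge)), function(p) {
    i <- match(bridge[p, 1], base$residue_ids)
    j <- match(bridge[p, 2], base$residue_ids)
    base$kirchhoff[i, j] != 0
  }, logical(1))
  bridge <- bridge[!existing, , drop = FALSE]
  wt <- gnm_add_contacts(base, bridge)
  mutant <- base
  list(structure = s, wt = wt, mutant = mutant, bridge_pairs = bridge,
       loop_region = "606-628", alpha3_region = "651-666")
}

#' Sample an ensemble from a Gaussian network model
#'
#' Draws `n_frames` i.i.d. conformations whose CA displacements follow a
#' zero-mean multivariate normal with covariance `scale * Gamma+`
#' independently along x, y and z, added to the structure's coordinates.
#' N and C atoms ride rigidly with their residue's CA. The expected
#' Cartesian cross-correlation map of the sample is exactly
#' [gnm_correlation] of the model.
#'
#' @param model a `gnm_model` built on `structure`
#' @param structure the [backbone_structure] providing mean coordinates
#' @param n_frames number of frames (>= 2)
#' @param scale per-axis fluctuation scale in Angstrom^2 (> 0)
#' @param seed integer seed
#' @param label ensemble label (default `"gnm"`)
#' @return a [trajectory_ensemble] with `equilibration_frame = 0`
#' @export
sample_gnm_ensemble <- function(model, structure, n_frames, scale = 1,
                                seed = 1L, label = "gnm") {
  stopifnot(inherits(model, "gnm_model"),
            inherits(structure, "backbone_structure"))
  if (!identical(model$residue_ids, structure$residue_ids))
    stop("model and structure have different residue ids")
  if (n_frames < 2L) stop("n_frames must be at least 2")
  if (scale <= 0) stop("scale must be positive")
  n <- length(model$residue_ids)
  n_modes <- length(model$mode_values)
  L <- model$mode_vectors %*% diag(sqrt(scale / model$mode_values),
                                   n_modes)
  disp <- with_seed(seed, {
    z <- array(stats::rnorm(n_modes * n_frames * 3L),
               dim = c(n_modes, n_frames, 3L))
    array(apply(z, 3L, function(zz) L %*% zz),
          dim = c(n, n_frames, 3L))
  })
  layout <- structure$layout
  ridx <- match(layout$residue_id, structure$residue_ids)
  base <- as.vector(t(structure$coords))
  xyz <- matrix(base, nrow = n_frames, ncol = length(base), byrow = TRUE)
  for (axis in 1:3) {
    cols <- seq(axis, length(base), by = 3L)
    xyz[, cols] <- xyz[, cols] + t(disp[ridx, , axis])
  }
  trajectory_ensemble(label, structure, xyz)
}

#' Generate labeled conformer-mixture ensembles
#'
#' Each state draws frames from a set of shared conformer centers with
#' its own population weights; frames add isotropic per-residue Gaussian
#' noise (applied rigidly to all atoms of a residue). This emulates a
#' population-shift scenario: states differ only in how often they visit
#' each conformer. The index of the generating center is recorded per
#' frame in the attribute `"center_index"` of each ensemble, providing
#' planted ground truth for clustering tests.
#'
#' @param centers list of [backbone_structure] conformers sharing one layout
#' @param weights named list: one non-negative weight vector (summing to 1,
#'   length = number of centers) per state label
#' @param n_frames frames per state (scalar or named vector)
#' @param noise per-residue Gaussian noise s.d. in Angstrom (scalar or one
#'   value per center)
#' @param seed integer seed
#' @return named list of [trajectory_ensemble] objects, one per label
#' @export
make_mixture_ensembles <- function(centers, weights, n_frames,
                                   noise = 0.5, seed = 1L) {
  stopifnot(length(centers) >= 1L, length(weights) >= 1L)
  for (cc in centers) check_same_layout(cc, centers[[1]])
  labels <- names(weights)
  if (is.null(labels) || any(labels == ""))
    stop("weights must be a named list (one entry per state label)")
  noise <- rep(noise, length.out = length(centers))
  if (length(centers) > 1L) {
    seps <- utils::combn(length(centers), 2L, function(p)
      kabsch_superpose(ca_coords(centers[[p[1]]]),
                       ca_coords(centers[[p[2]]]))$rmsd)
    if (max(noise) >= min(seps) / 2)
      warning("noise scale (", max(noise),
              " A) is at least half the minimum center separation (",
              format(min(seps), digits = 3),
              " A); clusters may merge")
  }
  if (is.null(names(n_frames)))
    n_frames <- stats::setNames(rep(n_frames, length.out = length(labels)),
                                labels)
  n_res <- length(centers[[1]]$residue_ids)
  layout <- centers[[1]]$layout
  ridx <- match(layout$residue_id, centers[[1]]$residue_ids)
  base <- lapply(centers, function(cc) as.vector(t(cc$coords)))
  out <- with_seed(seed, {
    res <- list()
    for (lab in labels) {
      w <- weights[[lab]]
      if (length(w) != length(centers) || any(w < 0) ||
          abs(sum(w) - 1) > 1e-9)
        stop("weights for '", lab,
             "' must be non-negative and sum to 1 over ", length(centers),
             " centers")
      f <- n_frames[[lab]]
      pick <- sample.int(length(centers), f, replace = TRUE, prob = w)
      xyz <- matrix(NA_real_, nrow = f, ncol = 3L * nrow(layout))
      for (t in seq_len(f)) {
        d <- matrix(stats::rnorm(3L * n_res, sd = noise[pick[t]]),
                    ncol = 3L)
        coords <- matrix(base[[pick[t]]], ncol = 3L, byrow = TRUE) +
          d[ridx, , drop = FALSE]
        xyz[t, ] <- as.vector(t(coords))
      }
      ens <- trajectory_ensemble(lab, centers[[1]], xyz)
      attr(ens, "center_index") <- pick
      res[[lab]] <- ens
    }
    res
  })
  out
}

#' Distinct conformer centers around a base structure
#'
#' Produces `n_centers` copies of a structure displaced by independent
#' Gaussian per-residue fields rescaled so that every center lies at the
#' stated CA RMSD from the base; in the high-dimensional coordinate space
#' the fields are near-orthogonal, so pairwise center separations are
#' close to `sqrt(2)` times that RMSD. All atoms of a residue share its
#' displacement.
#'
#' @param base a [backbone_structure]
#' @param n_centers number of conformers
#' @param rmsd_from_base CA RMSD of each center from the base (Angstrom)
#' @param seed integer seed
#' @return list of [backbone_structure] conformers
#' @export
make_conformer_centers <- function(base, n_centers, rmsd_from_base = 8,
                                   seed = 1L) {
  stopifnot(inherits(base, "backbone_structure"))
  n_res <- length(base$residue_ids)
  ridx <- match(base$layout$residue_id, base$residue_ids)
  with_seed(seed, lapply(seq_len(n_centers), function(m) {
    d <- matrix(stats::rnorm(3L * n_res), ncol = 3L)
    d <- d * rmsd_from_base / sqrt(mean(rowSums(d^2)))
    out <- base
    out$coords <- base$coords + d[ridx, , drop = FALSE]
    out
  }))
}

#' Canonical population-shift scenario of the KIX states
#'
#' A four-state conformer mixture emulating the redistribution of the KIX
#' ensemble across its binding states: three conformers (the
#' ternary-competent one plus two alternatives) with weights chosen so
#' that the fraction of frames sharing the ternary complex's conformer is
#' 58% for apo KIX, 99% for KIX:MLL and 47% for c-Myb:KIX, while the
#' ternary state occupies that conformer exclusively. Downstream
#' clustering + overlap analysis of these ensembles must recover those
#' planted percentages (up to binomial sampling error) and the ordering
#' MLL-bound > apo ~ c-Myb-bound.
#'
#' @param base base structure for the conformers (default: the built
#'   [kix_topology] backbone)
#' @param n_frames frames per state (default 2000)
#' @param noise within-conformer noise s.d. in Angstrom (default 0.5)
#' @param separation CA RMSD of each conformer from the base (default 10)
#' @param seed integer seed
#' @return list with `ensembles` (named list of four
#'   [trajectory_ensemble]s), `centers`, and `weights` (the planted
#'   population table)
#' @export
kix_shift_mixture <- function(base = NULL, n_frames = 2000L, noise = 0.5,
                              separation = 10, seed = 1L) {
  if (is.null(base)) base <- build_backbone(kix_topology(), seed = seed)
  centers <- make_conformer_centers(base, 3L, rmsd_from_base = separation,
                                    seed = seed + 1L)
  weights <- list(
    "KIX"            = c(0.58, 0.27, 0.15),
    "KIX:MLL"        = c(0.99, 0.01, 0.00),
    "c-Myb:KIX"      = c(0.47, 0.13, 0.40),
    "c-Myb:KIX:MLL"  = c(1.00, 0.00, 0.00))
  ens <- make_mixture_ensembles(centers, weights, n_frames, noise = noise,
                                seed = seed + 2L)
  list(ensembles = ens, centers = centers, weights = weights)
}
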
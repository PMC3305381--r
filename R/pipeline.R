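# End-to-end orchestration of the comparative workflow: per-state
# analysis (RMSD trend, equilibration, RMSF, correlation maps, region
# couplings), cross-state comparison (combinatorial clustering, radius
# sweep, overlap report, difference maps), all driven by one validated
# configuration. Outputs are plain CSV/PDB with comment-prefixed metadata
# headers and contain no timestamps, so identical config + seed
# reproduces byte-identical files.

#' Helical core residues of KIX
#'
#' Residue ids of the three helices (597-611, 623-640, 646-669), the
#' default "core" selection for RMSD against a reference structure. The
#' mobile L12/G2 loop is excluded on the grounds that the loop is the
#' flexible element; this preset is a documented assumption, not a
#' published list.
#'
#' @return integer vector of residue ids
#' @export
kix_core_selection <- function() {
  expand_residue_ranges(c("597-611", "623-640", "646-669"))
}

#' Functionally important binding-site residues of KIX
#'
#' Union of the MLL-binding and c-Myb-binding residues of the KIX domain
#' (groove residues of helices alpha1/alpha3 and the L12/alpha2 MLL
#' groove), the default selection for the clustering RMSD metric.
#'
#' @return integer vector of residue ids
#' @export
kix_binding_site_selection <- function() {
  sort(unique(c(599, 602, 603, 606, 607, 610, 611, 612, 613,
                624, 627, 628, 631, 639,
                650, 653, 654, 656, 657, 658, 660,
                662, 664, 665, 666, 668)))
}

config_defaults <- function() {
  list(schema_version = 1L,
       selections = list(core = NULL,        # NULL = all residues
                         clustering = NULL,
                         regions = list()),
       equilibration = list(mode = "auto", window_frac = 0.1,
                            slope_tol = 1e-3, sd_tol = 0.1,
                            fixed = list()),
       clustering = list(radius = 2.75,
                         sweep = c(1.5, 2.0, 2.75, 3.5, 4.0),
                         share_threshold = 0),
       out_dir = "allodyn_out",
       seed = 1L)
}

#' Validate a pipeline configuration
#'
#' Reads a YAML (or JSON) configuration file, applies documented defaults,
#' and checks paths, labels, ranges and numeric bounds. All violations
#' are collected and reported together, one line each.
#'
#' @param path configuration file path, or a named list of the same shape
#' @param check_paths verify that input files exist (default TRUE)
#' @return an object of class `run_config`; errors aggregate every
#'   violation found
#' @export
validate_config <- function(path, check_paths = TRUE) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(cfg)) stop("configuration must be a mapping")
  defaults <- config_defaults()
  defaulted <- character(0)
  for (k in names(defaults)) {
    if (is.null(cfg[[k]])) {
      cfg[[k]] <- defaults[[k]]
      if (!k %in% c("schema_version")) defaulted <- c(defaulted, k)
    } else if (is.list(defaults[[k]]) && is.list(cfg[[k]])) {
      for (k2 in names(defaults[[k]])) {
        if (is.null(cfg[[k]][[k2]])) {
          cfg[[k]][[k2]] <- defaults[[k]][[k2]]
          defaulted <- c(defaulted, paste0(k, ".", k2))
        }
      }
    }
  }
  errors <- character(0)
  add <- function(...) errors <<- c(errors, paste0(...))
  if (is.null(cfg$reference)) add("reference: missing (path to a PDB file)")
  else if (check_paths && !file.exists(cfg$reference))
    add(paste0("reference: file not found: ", cfg$reference))
  if (is.null(cfg$ensembles) || length(cfg$ensembles) == 0L) {
    add("ensembles: at least one (path, label) entry required")
  } else {
    labels <- character(0)
    for (i in seq_along(cfg$ensembles)) {
      e <- cfg$ensembles[[i]]
      if (is.null(e$path) || is.null(e$label)) {
        add(paste0("ensembles[", i, "]: needs both path and label"))
        next
      }
      if (check_paths && !file.exists(e$path))
        add(paste0("ensembles[", i, "]: file not found: ", e$path))
      if (e$label %in% labels)
        add(paste0("ensembles[", i, "]: duplicate label '", e$label, "'"))
      labels <- c(labels, e$label)
    }
  }
  for (sel in c("core", "clustering")) {
    v <- cfg$selections[[sel]]
    if (!is.null(v))
      tryCatch(cfg$selections[[sel]] <- expand_residue_ranges(v),
               error = function(e)
                 add(paste0("selections.", sel, ": ", conditionMessage(e))))
  }
  if (length(cfg$selections$regions) > 0L) {
    for (i in seq_along(cfg$selections$regions)) {
      p <- cfg$selections$regions[[i]]
      if (length(p) != 2L) {
        add(paste0("selections.regions[", i,
                   "]: needs exactly two ranges"))
        next
      }
      tryCatch({
        expand_residue_ranges(p[[1]]); expand_residue_ranges(p[[2]])
      }, error = function(e)
        add(paste0("selections.regions[", i, "]: ", conditionMessage(e))))
    }
  }
  if (!cfg$equilibration$mode %in% c("auto", "fixed"))
    add("equilibration.mode: must be 'auto' or 'fixed'")
  if (cfg$clustering$radius <= 0)
    add("clustering.radius: must be positive (got ",
        cfg$clustering$radius, ")")
  if (any(cfg$clustering$sweep <= 0))
    add("clustering.sweep: all radii must be positive")
  if (cfg$clustering$share_threshold < 0 ||
      cfg$clustering$share_threshold > 1)
    add("clustering.share_threshold: must lie in [0, 1]")
  if (length(errors) > 0L)
    stop("invalid configuration:\n  ",
         paste(errors, collapse = "\n  "), call. = FALSE)
  if (length(defaulted) > 0L)
    message("config defaults applied: ", paste(defaulted, collapse = ", "))
  structure(cfg, class = "run_config")
}

# two-column series CSV with metadata header
write_series_csv <- function(path, ids, values, id_name, value_name,
                             metadata = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(metadata))
    writeLines(sprintf("# %s: %s", k, metadata[[k]]), con)
  writeLines(paste(id_name, value_name, sep = ","), con)
  writeLines(paste(ids, format(values, digits = 10, trim = TRUE),
                   sep = ","), con)
  invisible(path)
}

write_table_csv <- function(path, df, metadata = list()) {
  con <- file(path, "w")
  for (k in names(metadata))
    writeLines(sprintf("# %s: %s", k, metadata[[k]]), con)
  close(con)
  suppressWarnings(utils::write.table(
    df, path, sep = ",", row.names = FALSE, quote = FALSE, append = TRUE))
  invisible(path)
}

load_config_inputs <- function(config) {
  reference <- read_structure(config$reference)
  ensembles <- lapply(config$ensembles, function(e)
    read_ensemble(e$path, e$label))
  names(ensembles) <- vapply(ensembles, function(e) e$label, character(1))
  list(reference = reference, ensembles = ensembles)
}

# set the equilibration index of one ensemble per the config policy
apply_equilibration <- function(ensemble, reference, config) {
  eq <- config$equilibration
  if (identical(eq$mode, "fixed")) {
    fixed <- eq$fixed[[ensemble$label]]
    ensemble$equilibration_frame <-
      if (is.null(fixed)) 0L else as.integer(fixed)
    return(ensemble)
  }
  series <- rmsd_series(ensemble, reference, config$selections$core)
  window <- max(2L, as.integer(round(eq$window_frac * length(series))))
  if (length(series) >= 2L * window) {
    idx <- suppressWarnings(
      detect_equilibration(series, window, eq$slope_tol, eq$sd_tol))
    ensemble$equilibration_frame <- as.integer(idx) - 1L
  }
  ensemble
}

state_output_inventory <- function(out_dir, label) {
  safe <- gsub("[^A-Za-z0-9._-]", "_", label)
  file.path(out_dir, paste0(safe, c(
    "_rmsd.csv", "_rmsf.csv", "_average.pdb",
    "_dccm_cartesian.csv", "_dccm_pseudo_dihedral.csv",
    "_dccm_phi.csv", "_dccm_psi.csv", "_region_coupling.csv")))
}

#' Per-state analysis of every configured ensemble
#'
#' For each labeled ensemble: RMSD series against the reference over the
#' core selection, equilibration detection (or the configured fixed
#' index), alignment, average structure, RMSF profile, the Cartesian and
#' phi/psi/pseudo-dihedral correlation maps, and the region-coupling
#' table for all configured region pairs. A failing label is reported and
#' skipped; the remaining labels still run.
#'
#' @param config a validated `run_config` (see [validate_config])
#' @return invisibly, a list with per-label results and a `failures`
#'   character vector (empty on full success)
#' @export
run_state_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  reference <- read_structure(config$reference)
  results <- list(); failures <- character(0)
  for (entry in config$ensembles) {
    label <- entry$label
    res <- tryCatch(
      analyze_one_state(read_ensemble(entry$path, label), reference,
                        config),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, label)
      message("state '", label, "' failed: ", conditionMessage(res))
    } else {
      results[[label]] <- res
      message("state '", label, "': equilibration_frame = ",
              res$equilibration_frame, ", ", res$n_used, " frames used")
    }
  }
  invisible(list(results = results, failures = failures))
}

analyze_one_state <- function(ensemble, reference, config) {
  out <- state_output_inventory(config$out_dir, ensemble$label)
  core <- config$selections$core
  series <- rmsd_series(ensemble, reference, core)
  ensemble <- apply_equilibration(ensemble, reference, config)
  meta <- list(ensemble = ensemble$label,
               reference = config$reference,
               selection = if (is.null(core)) "all"
                           else paste(core, collapse = " "),
               equilibration_frame = ensemble$equilibration_frame)
  write_series_csv(out[1], seq_along(series), series, "frame", "rmsd_A",
                   meta)
  aligned <- align_ensemble(ensemble, reference, core)
  avg <- average_structure(aligned, reference, core)
  write_structure(avg, out[3])
  prof <- rmsf(aligned, avg)
  write_series_csv(out[2], names(prof), prof, "residue", "rmsf_A", meta)
  maps <- list(cartesian = cartesian_cross_correlation(aligned))
  for (kind in c("pseudo_dihedral", "phi", "psi")) {
    maps[[kind]] <- angular_cross_correlation(
      torsion_series(aligned, kind),
      equilibration_frame = aligned$equilibration_frame,
      ensemble_label = aligned$label)
  }
  write_matrix(as_matrix_record(maps$cartesian), out[4])
  write_matrix(as_matrix_record(maps$pseudo_dihedral), out[5])
  write_matrix(as_matrix_record(maps$phi), out[6])
  write_matrix(as_matrix_record(maps$psi), out[7])
  couplings <- NULL
  if (length(config$selections$regions) > 0L) {
    rows <- list()
    for (pair in config$selections$regions) {
      for (kind in names(maps)) {
        rc <- region_coupling(maps[[kind]], pair[[1]], pair[[2]])
        rows[[length(rows) + 1L]] <- data.frame(
          kind = kind,
          region_a = paste0(min(rc$region_a), "-", max(rc$region_a)),
          region_b = paste0(min(rc$region_b), "-", max(rc$region_b)),
          score = rc$score, abs_score = rc$abs_score,
          n_pairs = rc$n_pairs, stringsAsFactors = FALSE)
      }
    }
    couplings <- do.call(rbind, rows)
    write_table_csv(out[8], couplings, meta)
  }
  list(equilibration_frame = ensemble$equilibration_frame,
       n_used = length(equilibrated_frames(ensemble)),
       rmsd = series, rmsf = prof, average = avg, maps = maps,
       couplings = couplings, aligned = aligned)
}

#' Cross-state comparison: clustering, overlap and difference maps
#'
#' Aligns every ensemble to the reference, computes the global average
#' structure of the merged post-equilibration frames, re-aligns all
#' frames to it, then runs the radius-bounded combinatorial clustering at
#' the configured radius and the radius sweep, writes occupancy and
#' pairwise overlap tables, and the Cartesian difference map plus
#' region-coupling deltas for every label pair.
#'
#' @param config a validated `run_config` with at least two ensembles
#' @return invisibly, a list with `model` (the `cluster_model`), `sweep`,
#'   `report` (the `overlap_report`) and `difference_maps`
#' @export
run_comparative <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (length(config$ensembles) < 2L)
    stop("comparative analysis needs at least two ensembles")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- load_config_inputs(config)
  core <- config$selections$core
  ensembles <- lapply(inputs$ensembles, function(e)
    align_ensemble(apply_equilibration(e, inputs$reference, config),
                   inputs$reference, core))
  # global average (all atoms) of the merged equilibrated frames
  merged_xyz <- do.call(rbind, lapply(ensembles, function(e)
    e$xyz[equilibrated_frames(e), , drop = FALSE]))
  global_avg <- inputs$reference
  global_avg$coords <- matrix(colMeans(merged_xyz), ncol = 3L, byrow = TRUE)
  ensembles <- lapply(ensembles, align_ensemble, reference = global_avg,
                      selection = core)
  sel <- config$selections$clustering
  model <- combinatorial_cluster(ensembles, config$clustering$radius,
                                 selection = sel, seed = config$seed)
  sweep_tab <- sweep_radius(ensembles, config$clustering$sweep,
                            selection = sel, seed = config$seed)
  report <- overlap_report(model, config$clustering$share_threshold)
  meta <- list(radius = config$clustering$radius,
               selection = if (is.null(sel)) "all"
                           else paste(sel, collapse = " "),
               share_threshold = config$clustering$share_threshold,
               seed = config$seed)
  write_table_csv(file.path(config$out_dir, "cluster_assignments.csv"),
                  model$assignments, meta)
  occ <- as.data.frame.matrix(unclass(model$occupancy))
  occ <- cbind(label = rownames(occ), occ)
  write_table_csv(file.path(config$out_dir, "cluster_occupancy.csv"),
                  occ, meta)
  write_table_csv(file.path(config$out_dir, "radius_sweep.csv"),
                  sweep_tab, meta)
  ov <- as.data.frame.matrix(report$overlap)
  ov <- cbind(query = rownames(ov), ov)
  write_table_csv(file.path(config$out_dir, "overlap.csv"), ov, meta)
  # pairwise Cartesian difference maps
  maps <- lapply(ensembles, cartesian_cross_correlation)
  labels <- names(maps)
  diffs <- list()
  if (length(labels) >= 2L) {
    for (i in seq_len(length(labels) - 1L)) {
      for (j in (i + 1L):length(labels)) {
        dm <- difference_map(maps[[i]], maps[[j]])
        key <- paste0(gsub("[^A-Za-z0-9._-]", "_", labels[i]), "_vs_",
                      gsub("[^A-Za-z0-9._-]", "_", labels[j]))
        write_matrix(dm, file.path(config$out_dir,
                                   paste0("diff_", key, ".csv")))
        diffs[[key]] <- dm
      }
    }
  }
  invisible(list(model = model, sweep = sweep_tab, report = report,
                 difference_maps = diffs, ensembles = ensembles,
                 global_average = global_avg))
}
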
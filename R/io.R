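# Reading and writing of structures (PDB), ensembles (multi-model PDB) and
# labeled matrices (CSV with comment-prefixed metadata header).
#
# PDB parsing is delegated to bio3d::read.pdb; this layer enforces the
# backbone-only single-chain contract: exactly one chain is analyzed,
# insertion codes are rejected, alternate locations resolve to the highest
# occupancy, and hydrogens/side chains are dropped. Multi-model writing is
# done directly (fixed-width ATOM records) because bio3d's writer emits a
# single model.

BACKBONE_ATOMS <- c("N", "CA", "C")

# normalize a bio3d atom table to the backbone of one chain
select_backbone_atoms <- function(atom, chain = NULL, path = "") {
  chains <- unique(atom$chain)
  chains <- chains[!is.na(chains)]
  if (length(chains) == 0L) chains <- "A"
  if (is.null(chain)) {
    if (length(chains) > 1L)
      stop("file ", path, " contains chains ",
           paste(chains, collapse = ", "),
           "; pass an explicit `chain` selection")
    chain <- chains[1]
  }
  sel <- atom$type == "ATOM" &
    (is.na(atom$chain) | atom$chain == chain) &
    atom$elety %in% BACKBONE_ATOMS
  atom <- atom[sel, , drop = FALSE]
  if (nrow(atom) == 0L)
    stop("no backbone atoms found for chain ", chain, " in ", path)
  if (any(!is.na(atom$insert)))
    stop("insertion codes are not supported (residue ",
         atom$resno[which(!is.na(atom$insert))[1]], ")")
  # alternate locations: keep the highest-occupancy record per atom
  if (any(!is.na(atom$alt))) {
    key <- paste(atom$resno, atom$elety)
    occ <- ifelse(is.na(atom$o), 1, atom$o)
    keep <- !logical(nrow(atom))
    for (k in unique(key[duplicated(key)])) {
      idx <- which(key == k)
      keep[idx] <- FALSE
      keep[idx[which.max(occ[idx])]] <- TRUE
    }
    atom <- atom[keep, , drop = FALSE]
  }
  attr(atom, "chain_used") <- chain
  atom
}

backbone_from_atom_table <- function(atom, chain) {
  resno <- unique(atom$resno)
  ord <- order(resno)
  resno <- resno[ord]
  # order atoms N, CA, C within each residue, residues by number
  rows <- unlist(lapply(resno, function(r) {
    idx <- which(atom$resno == r)
    idx[order(match(atom$elety[idx], BACKBONE_ATOMS))]
  }))
  atom <- atom[rows, , drop = FALSE]
  missing_ca <- resno[!resno %in% atom$resno[atom$elety == "CA"]]
  if (length(missing_ca) > 0L)
    stop("missing CA for residue ", missing_ca[1])
  resname <- vapply(resno, function(r)
    atom$resid[atom$resno == r][1], character(1))
  backbone_structure(
    residue_ids = resno,
    residue_names = resname,
    chain_id = chain,
    coords = cbind(atom$x, atom$y, atom$z),
    layout = data.frame(residue_id = atom$resno, atom = atom$elety,
                        stringsAsFactors = FALSE))
}

#' Read a single-model PDB file as a backbone structure
#'
#' Parses the first (or only) MODEL of a PDB file, keeping the backbone
#' N/CA/C atoms of one chain. Hydrogens, side chains, HETATM records and
#' any other chains are ignored. Alternate locations are resolved to the
#' highest-occupancy record; insertion codes are rejected.
#'
#' @param path path to a PDB file
#' @param chain chain identifier to extract; default: the only chain
#'   present (an error if the file holds several).
#' @return a [backbone_structure]
#' @export
read_structure <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  atom <- select_backbone_atoms(pdb$atom, chain, path)
  backbone_from_atom_table(atom, attr(atom, "chain_used"))
}

#' Read a multi-model PDB file as a trajectory ensemble
#'
#' Every MODEL becomes one frame, in file order. All models must share an
#' identical atom layout; a mismatch is an error naming the offending model.
#'
#' @param path path to a multi-model PDB file (MODEL/ENDMDL records)
#' @param label state name attached to the ensemble
#' @param chain chain to extract (see [read_structure])
#' @param frame_interval time per frame in ps (informational)
#' @return a [trajectory_ensemble] with `equilibration_frame = 0`
#' @export
read_ensemble <- function(path, label, chain = NULL, frame_interval = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0L)
    stop("no MODEL records found in ", path,
         " (not a multi-model ensemble file)")
  ends <- grep("^ENDMDL", lines)
  if (length(ends) != length(starts))
    stop("unbalanced MODEL/ENDMDL records in ", path)
  counts <- vapply(seq_along(starts), function(i)
    sum(grepl("^ATOM", lines[starts[i]:ends[i]])), integer(1))
  if (length(unique(counts)) != 1L)
    stop("model ", which(counts != counts[1])[1],
         " has a different atom count (", counts[which(counts != counts[1])[1]],
         " vs ", counts[1], ")")
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                         verbose = FALSE)
  atom <- select_backbone_atoms(pdb$atom, chain, path)
  template <- backbone_from_atom_table(atom, attr(atom, "chain_used"))
  # map template atom order back to xyz columns of the multi-model matrix
  rows <- match(paste(template$layout$residue_id, template$layout$atom),
                paste(atom$resno, atom$elety))
  src_rows <- as.integer(rownames(atom))[rows]
  xyz <- pdb$xyz[, atom_xyz_cols(src_rows), drop = FALSE]
  trajectory_ensemble(label, template, xyz, frame_interval = frame_interval)
}

fmt_atom_line <- function(serial, atom, resname, chain, resno, xyz) {
  sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          serial, ifelse(nchar(atom) < 4, paste0(" ", atom), atom),
          resname, chain, resno, xyz[1], xyz[2], xyz[3])
}

structure_atom_lines <- function(structure, coords = NULL) {
  if (is.null(coords)) coords <- structure$coords
  layout <- structure$layout
  resname <- structure$residue_names[match(layout$residue_id,
                                           structure$residue_ids)]
  vapply(seq_len(nrow(layout)), function(i)
    fmt_atom_line(i, layout$atom[i], resname[i], structure$chain_id,
                  layout$residue_id[i], coords[i, ]),
    character(1))
}

#' Write a backbone structure as a single-model PDB file
#' @param structure a [backbone_structure]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_structure <- function(structure, path) {
  stopifnot(inherits(structure, "backbone_structure"))
  writeLines(c(structure_atom_lines(structure), "TER", "END"), path)
  invisible(path)
}

#' Write a trajectory ensemble as a multi-model PDB file
#' @param ensemble a [trajectory_ensemble]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(ensemble))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(structure_atom_lines(ensemble$template,
                                    frame_coords(ensemble, f)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Construct a labeled matrix record
#'
#' A thin container tying a dense numeric matrix to row/column labels, a
#' kind tag and free-form metadata, used for correlation maps, difference
#' maps and report tables on disk.
#'
#' @param values numeric matrix
#' @param row_labels,col_labels label vectors matching the dimensions
#' @param kind free-text kind tag (e.g. `"cartesian"`, `"difference"`)
#' @param metadata named list of strings recorded in the file header
#' @return an object of class `matrix_record`
#' @export
matrix_record <- function(values, row_labels, col_labels = row_labels,
                          kind = "matrix", metadata = list()) {
  values <- as.matrix(values)
  if (nrow(values) != length(row_labels) ||
      ncol(values) != length(col_labels))
    stop("matrix dimensions (", nrow(values), "x", ncol(values),
         ") do not match label lengths (", length(row_labels), ", ",
         length(col_labels), ")")
  structure(list(values = unname(values),
                 row_labels = as.character(row_labels),
                 col_labels = as.character(col_labels),
                 kind = kind, metadata = metadata),
            class = "matrix_record")
}

#' @export
print.matrix_record <- function(x, ...) {
  cat("<matrix_record>", x$kind, "-", nrow(x$values), "x", ncol(x$values), "\n")
  invisible(x)
}

#' Write a matrix record as CSV
#'
#' The file starts with comment-prefixed metadata lines (`# key: value`),
#' then a header row of column labels and one row per matrix row with the
#' row label in the first field. Full double precision is retained, so the
#' file round-trips through [read_matrix] to near machine precision.
#'
#' @param record a [matrix_record]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_matrix <- function(record, path) {
  stopifnot(inherits(record, "matrix_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind: %s", record$kind), con)
  for (k in names(record$metadata))
    writeLines(sprintf("# %s: %s", k, record$metadata[[k]]), con)
  writeLines(paste(c("label", record$col_labels), collapse = ","), con)
  body <- vapply(seq_len(nrow(record$values)), function(i)
    paste(c(record$row_labels[i],
            format(record$values[i, ], digits = 17, trim = TRUE,
                   scientific = TRUE)), collapse = ","),
    character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read a matrix record written by [write_matrix]
#' @param path path to the CSV file
#' @return a [matrix_record]
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines)
  meta <- list()
  kind <- "matrix"
  for (l in lines[meta_lines]) {
    m <- regmatches(l, regexec("^#\\s*([^:]+):\\s*(.*)$", l))[[1]]
    if (length(m) == 3L) {
      if (m[2] == "kind") kind <- m[3] else meta[[m[2]]] <- m[3]
    }
  }
  body <- lines[setdiff(seq_along(lines), meta_lines)]
  if (length(body) < 2L) stop("no matrix body in ", path)
  header <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  col_labels <- header[-1]
  cells <- strsplit(body[-1], ",", fixed = TRUE)
  bad <- which(lengths(cells) != length(header))
  if (length(bad) > 0L)
    stop("row ", bad[1], " of ", path, " has ", lengths(cells)[bad[1]] - 1L,
         " values but the header names ", length(col_labels), " columns")
  row_labels <- vapply(cells, `[`, character(1), 1L)
  values <- do.call(rbind, lapply(cells, function(x) as.numeric(x[-1])))
  matrix_record(values, row_labels, col_labels, kind = kind, metadata = meta)
}
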
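#' Read a peptide-level uptake table
#'
#' Reads comma-separated deuterium uptake tables in either the package's
#' canonical layout or the column layout exported by DynamX "state data"
#' files. DynamX exposures are given in minutes and are converted to
#' seconds on read; uptake values are never rescaled. Rows with a missing
#' uptake value are dropped with a message. Tables read here are marked as
#' back-exchange *uncorrected*: correction is an explicit pipeline stage
#' ([correct_backexchange()]).
#'
#' @param path Path to a CSV file.
#' @param dialect `"canonical"` (columns `protein,state,start,end,sequence,
#'   exposure_s,uptake_Da,sd_Da,n_reps`) or `"dynamx"` (columns `Protein,
#'   State,Start,End,Sequence,Exposure,Uptake,Uptake SD`, exposure in
#'   minutes).
#' @param col_map Optional named character vector remapping header names for
#'   file variants, e.g. `c(Uptake = "Center")`; names are the expected
#'   dialect headers, values the headers found in the file.
#' @return A validated uptake tibble in canonical layout.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' tbl <- simulate_uptake(
#'   generate_ground_truth(30, seed = 1),
#'   generate_peptide_map(30, seed = 1),
#'   seed = 1
#' )
#' write_uptake_table(tbl, tf)
#' identical(read_uptake_table(tf), tbl)
#' @export
read_uptake_table <- function(path, dialect = c("canonical", "dynamx"),
                              col_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  # read as text and convert with base R's correctly rounded strtod, so a
  # table written at full precision re-reads bit-identically
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (!is.null(col_map)) {
    for (want in names(col_map)) {
      if (col_map[[want]] %in% names(raw)) {
        names(raw)[names(raw) == col_map[[want]]] <- want
      }
    }
  }
  expected <- switch(dialect,
    canonical = canonical_cols,
    dynamx = c("Protein", "State", "Start", "End", "Sequence",
               "Exposure", "Uptake", "Uptake SD")
  )
  unmatched <- setdiff(expected, names(raw))
  if (length(unmatched) > 0) {
    abort(paste0(
      "header does not match dialect '", dialect,
      "': first unmatched column is '", unmatched[1], "'"
    ))
  }
  tbl <- if (dialect == "canonical") {
    out <- raw[canonical_cols]
    for (cn in c("exposure_s", "uptake_Da", "sd_Da")) {
      out[[cn]] <- as.numeric(out[[cn]])
    }
    out
  } else {
    tibble(
      protein = raw$Protein,
      state = raw$State,
      start = as.integer(raw$Start),
      end = as.integer(raw$End),
      sequence = raw$Sequence,
      exposure_s = as.numeric(raw$Exposure) * 60,
      uptake_Da = as.numeric(raw$Uptake),
      sd_Da = as.numeric(raw$`Uptake SD`),
      n_reps = if ("n_reps" %in% names(raw)) raw$n_reps else NA_integer_
    )
  }
  n_missing <- sum(!complete.cases(tbl$uptake_Da))
  if (n_missing > 0) {
    inform(paste0("dropped ", n_missing, " row(s) with missing uptake"))
    tbl <- tbl[complete.cases(tbl$uptake_Da), ]
  }
  tbl$start <- as.integer(tbl$start)
  tbl$end <- as.integer(tbl$end)
  tbl$n_reps <- as.integer(tbl$n_reps)
  validate_uptake_table(tbl)
  set_corrected(as_tibble(tbl), FALSE)
}

#' Write an uptake table as canonical CSV
#'
#' @param table A canonical uptake table ([validate_uptake_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_uptake_table <- function(table, path) {
  validate_uptake_table(table, check_timepoints = FALSE)
  out <- table[canonical_cols]
  # full round-trip precision: a written table re-reads bit-identically
  for (cn in c("exposure_s", "uptake_Da", "sd_Da")) {
    out[[cn]] <- sprintf("%.17g", out[[cn]])
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Export an uptake table (plus provenance) as JSON
#'
#' Archival export: the rows in canonical layout together with the
#' back-exchange correction state recorded on the table.
#'
#' @inheritParams write_uptake_table
#' @return `path`, invisibly.
#' @export
export_uptake_json <- function(table, path) {
  validate_uptake_table(table, check_timepoints = FALSE)
  payload <- list(
    corrected = is_corrected(table),
    be_frac = attr(table, "be_frac") %||% NA_real_,
    rows = as.data.frame(table[canonical_cols])
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Paint a per-residue map onto the B-factor column of a PDB file
#'
#' Writes a copy of `structure` in which the B-factor of every atom of a
#' mapped residue carries the map value (rounded to two decimals, the PDB
#' field precision) and unmapped residues carry a sentinel. This is the
#' standard route for colouring differential-uptake or protection-factor
#' results onto a structure in molecular viewers.
#'
#' @param structure A `bio3d` `pdb` object or a path to a PDB file.
#' @param map A data frame with columns `resno` and `value` (or a named
#'   numeric vector, names = residue numbers).
#' @param path Output PDB path.
#' @param sentinel B-factor for residues absent from the map (default -1).
#' @param chain Restrict painting to one chain id (default: all chains).
#' @return `path`, invisibly. Residue numbers in `map` that do not occur in
#'   the structure are reported in a warning.
#' @export
write_residue_map_pdb <- function(structure, map, path, sentinel = -1,
                                  chain = NULL) {
  pdb <- if (inherits(structure, "pdb")) structure else bio3d::read.pdb(structure)
  map <- as_residue_map(map)
  atom_res <- pdb$atom$resno
  sel <- rep(TRUE, length(atom_res))
  if (!is.null(chain)) sel <- pdb$atom$chain %in% chain
  absent <- setdiff(map$resno, unique(atom_res[sel]))
  if (length(absent) > 0) {
    warn(paste0(
      "residue(s) absent from structure, not painted: ",
      paste(absent, collapse = ", ")
    ))
  }
  b <- rep(round(sentinel, 2), length(atom_res))
  idx <- match(atom_res, map$resno)
  hit <- !is.na(idx) & sel
  b[hit] <- round(map$value[idx[hit]], 2)
  pdb$atom$b <- b
  bio3d::write.pdb(pdb, file = path)
  invisible(path)
}

#' Read a per-residue map back from a painted PDB file
#'
#' Inverse of [write_residue_map_pdb()]: recovers one value per residue
#' from the B-factor column, dropping sentinel-valued residues.
#'
#' @param path PDB file written by [write_residue_map_pdb()].
#' @param sentinel Sentinel used when writing.
#' @return A tibble with columns `resno`, `value`.
#' @export
read_residue_map_pdb <- function(path, sentinel = -1) {
  pdb <- bio3d::read.pdb(path)
  per_res <- pdb$atom |>
    dplyr::distinct(.data$resno, .data$b) |>
    dplyr::group_by(.data$resno) |>
    dplyr::summarise(value = .data$b[1], .groups = "drop")
  per_res <- per_res[abs(per_res$value - round(sentinel, 2)) > 1e-9, ]
  tibble(resno = as.integer(per_res$resno), value = per_res$value)
}

## Accept either a (resno, value) data frame or a named numeric vector.
as_residue_map <- function(map) {
  if (is.data.frame(map)) {
    stopifnot(all(c("resno", "value") %in% names(map)))
    tibble(resno = as.integer(map$resno), value = as.numeric(map$value))
  } else {
    if (is.null(names(map))) abort("residue map vector must be named by residue number")
    tibble(resno = as.integer(names(map)), value = as.numeric(map))
  }
}
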
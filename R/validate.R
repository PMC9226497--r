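## Internal schema checks shared by the readers, the simulator and the
## pipeline stages. An uptake table is an ordinary tibble in "canonical"
## layout; stage provenance (back-exchange correction state) travels in the
## "corrected" attribute so that a table is self-describing.

canonical_cols <- c(
  "protein", "state", "start", "end", "sequence",
  "exposure_s", "uptake_Da", "sd_Da", "n_reps"
)

aa_alphabet <- c(
  "A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

#' Validate an uptake table
#'
#' Checks the canonical peptide-level uptake layout: one row per
#' (protein, state, peptide span, exposure), non-negative uptake and
#' standard deviation, peptide sequences consistent with their residue
#' spans, and uniqueness of the row key. Called by the readers and by
#' every pipeline stage that consumes a table.
#'
#' @param table A data frame with columns `protein`, `state`, `start`,
#'   `end`, `sequence`, `exposure_s`, `uptake_Da`, `sd_Da`, `n_reps`.
#' @param check_timepoints If `TRUE`, warn when peptides within a state do
#'   not share an identical set of exposure times.
#' @return The table, invisibly, as a tibble (errors otherwise).
#' @export
validate_uptake_table <- function(table, check_timepoints = TRUE) {
  table <- as_tibble(table)
  missing <- setdiff(canonical_cols, names(table))
  if (length(missing) > 0) {
    abort(paste0(
      "uptake table is missing column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  if (any(table$start > table$end)) {
    bad <- which(table$start > table$end)[1]
    abort(paste0("row ", bad, ": start exceeds end"))
  }
  len_ok <- nchar(table$sequence) == table$end - table$start + 1
  if (!all(len_ok)) {
    abort(paste0(
      "row ", which(!len_ok)[1],
      ": sequence length does not match residue span"
    ))
  }
  letters_used <- unique(strsplit(paste(table$sequence, collapse = ""), "")[[1]])
  alien <- setdiff(letters_used, aa_alphabet)
  if (length(alien) > 0) {
    abort(paste0(
      "sequence contains non-standard residue letter(s): ",
      paste(alien, collapse = ", ")
    ))
  }
  if (any(table$exposure_s < 0)) {
    abort(paste0("row ", which(table$exposure_s < 0)[1], ": negative exposure"))
  }
  neg <- which(table$uptake_Da < 0)
  if (length(neg) > 0) {
    abort(paste0("row ", neg[1], ": negative uptake (", table$uptake_Da[neg[1]], " Da)"))
  }
  if (any(table$sd_Da < 0)) {
    abort(paste0("row ", which(table$sd_Da < 0)[1], ": negative standard deviation"))
  }
  key <- paste(table$protein, table$state, table$start, table$end, table$exposure_s)
  if (anyDuplicated(key) > 0) {
    abort(paste0(
      "duplicate measurement key at row ", anyDuplicated(key),
      " (protein, state, start, end, exposure_s must be unique)"
    ))
  }
  if (check_timepoints) {
    tp <- table |>
      dplyr::group_by(.data$protein, .data$state, .data$start, .data$end) |>
      dplyr::summarise(
        tps = paste(sort(unique(.data$exposure_s)), collapse = ","),
        .groups = "drop_last"
      ) |>
      dplyr::summarise(n_sched = dplyr::n_distinct(.data$tps), .groups = "drop")
    if (any(tp$n_sched > 1)) {
      warn("timepoint schedules differ between peptides within a state")
    }
  }
  invisible(table)
}

## TRUE if the table has been through correct_backexchange()
is_corrected <- function(table) isTRUE(attr(table, "corrected"))

set_corrected <- function(table, value = TRUE, be_frac = NULL) {
  attr(table, "corrected") <- value
  if (!is.null(be_frac)) attr(table, "be_frac") <- be_frac
  table
}

## peptide identifier used in messages and result tables
peptide_id <- function(start, end) paste0(start, "-", end)
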
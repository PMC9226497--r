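#' Count exchangeable amides of a peptide
#'
#' The maximum observable deuterium uptake of a peptide under standard
#' quench-and-digest workflows: its length minus the N-terminal residue(s)
#' whose amide deuterium is lost during analysis, minus prolines (which
#' have no backbone amide proton) at the remaining positions. The
#' single-residue skip is the convention used by DynamX-style
#' maximum-uptake counting; a two-residue skip is available for workflows
#' that assume the second amide also back-exchanges completely.
#'
#' @param sequence Peptide sequence (one-letter codes), or a data frame
#'   with a `sequence` column (the count is then computed per row).
#' @param convention `"skip_first"` (default) or `"skip_first_two"`.
#' @return Integer count(s), >= 0.
#' @examples
#' exchangeable_amides("APGA") # 2: A1 skipped, P excluded, G and A count
#' @export
exchangeable_amides <- function(sequence,
                                convention = c("skip_first", "skip_first_two")) {
  convention <- match.arg(convention)
  if (is.data.frame(sequence)) sequence <- sequence$sequence
  skip <- if (convention == "skip_first") 1L else 2L
  vapply(sequence, function(s) {
    aa <- strsplit(s, "")[[1]]
    if (length(aa) <= skip) return(0L)
    aa <- aa[-seq_len(skip)]
    sum(aa != "P")
  }, integer(1), USE.NAMES = FALSE)
}

#' Correct an uptake table for back-exchange against a template peptide
#'
#' Estimates the global back-exchange fraction from a template peptide
#' assumed to be fully exchanged at its plateau (the standard
#' fully-deuterated-control surrogate used by DECA-style correction):
#' `be_frac = 1 - D_template(plateau) / N_exch(template)`. Every uptake and
#' standard deviation in the table is then divided by `1 - be_frac`, and
#' the table is flagged as corrected.
#'
#' @param table A canonical uptake table (uncorrected).
#' @param template Template peptide as `c(start, end)`, or a one-row data
#'   frame with `start` and `end`. When the table holds several states the
#'   template is taken from `template_state` (the template peptide must be
#'   present there); the correction factor is applied to all states, as the
#'   loss is a property of the quench/separation stage, not of the state.
#' @param template_state State from which the template plateau is read
#'   (default: the state with the largest template uptake).
#' @param plateau `"last_timepoint"` (default; with a short labeling
#'   schedule a fitted plateau is unstable for fast templates) or
#'   `"fitted"` (single-exponential plateau, [fit_uptake()]).
#' @param convention Passed to [exchangeable_amides()].
#' @return A list of class `hdx_backexchange` with elements `template`
#'   (tibble), `be_frac`, and `corrected` (the corrected table, flagged).
#' @examples
#' gt <- generate_ground_truth(40, base_log10_pf = 0, seed = 2)
#' tbl <- simulate_uptake(gt, generate_peptide_map(40, seed = 2),
#'                        backexchange_frac = 0.25, seed = 2)
#' res <- correct_backexchange(tbl)
#' res$be_frac
#' @export
correct_backexchange <- function(table, template = NULL,
                                 template_state = NULL,
                                 plateau = c("last_timepoint", "fitted"),
                                 convention = c("skip_first", "skip_first_two")) {
  plateau <- match.arg(plateau)
  convention <- match.arg(convention)
  validate_uptake_table(table, check_timepoints = FALSE)
  if (is_corrected(table)) {
    warn("table is already flagged as corrected; correcting again")
  }
  if (is.null(template)) {
    # default template: the peptide closest to full exchange at the last
    # timepoint (largest uptake / N_exch ratio across states); peptides
    # with fewer than 3 exchangeable amides are avoided when possible,
    # their single-amide noise making the loss estimate unstable
    cand <- table |>
      dplyr::group_by(.data$start, .data$end, .data$sequence) |>
      dplyr::summarise(u = max(.data$uptake_Da), .groups = "drop")
    cand$n_exch <- exchangeable_amides(cand$sequence, convention)
    if (any(cand$n_exch >= 3)) cand <- cand[cand$n_exch >= 3, ]
    ratio <- cand$u / pmax(1L, cand$n_exch)
    template <- c(cand$start[which.max(ratio)], cand$end[which.max(ratio)])
  }
  if (is.data.frame(template)) template <- c(template$start[1], template$end[1])
  trows <- table[table$start == template[1] & table$end == template[2], ]
  if (nrow(trows) == 0) {
    abort(paste0("template peptide ", peptide_id(template[1], template[2]),
                 " absent from table"))
  }
  if (all(trows$exposure_s == 0)) {
    abort("template peptide has no nonzero timepoint")
  }
  if (is.null(template_state)) {
    template_state <- trows$state[which.max(trows$uptake_Da)]
  }
  trows <- trows[trows$state == template_state, ]
  n_exch <- exchangeable_amides(trows$sequence[1], convention)
  plateau_uptake <- if (plateau == "last_timepoint") {
    trows$uptake_Da[which.max(trows$exposure_s)]
  } else {
    fit <- fit_uptake(trows)
    fit$A[1]
  }
  be_frac <- 1 - plateau_uptake / n_exch
  if (be_frac < 0) {
    abort(paste0(
      "template uptake exceeds its theoretical maximum (ratio ",
      signif(plateau_uptake / n_exch, 4), "); not a valid template"
    ))
  }
  factor <- 1 / (1 - be_frac)
  corrected <- table
  corrected$uptake_Da <- corrected$uptake_Da * factor
  corrected$sd_Da <- corrected$sd_Da * factor
  corrected <- set_corrected(corrected, TRUE, be_frac = be_frac)
  structure(
    list(
      template = tibble(
        start = as.integer(template[1]), end = as.integer(template[2]),
        sequence = trows$sequence[1], state = template_state,
        n_exch = n_exch, plateau_uptake = plateau_uptake
      ),
      be_frac = be_frac,
      corrected = corrected
    ),
    class = "hdx_backexchange"
  )
}

#' @export
print.hdx_backexchange <- function(x, ...) {
  cat("<hdx_backexchange> template ",
      peptide_id(x$template$start, x$template$end),
      " (", x$template$state, "), be_frac = ", signif(x$be_frac, 4), "\n",
      sep = "")
  invisible(x)
}

#' Resolve overhanging regions by overlapping-peptide subtraction
#'
#' For every pair of peptides within a state where one span strictly
#' contains the other and the two share exactly one endpoint, the uptake of
#' the overhanging region (the residues unique to the longer peptide) is
#' the difference of the two uptakes, with the uncertainty propagated in
#' quadrature. A difference is accepted as a resolved measurement only when
#' it exceeds `sigma_multiplier` times its propagated uncertainty — the
#' conservative criterion under which subtraction adds information rather
#' than noise.
#'
#' @param table Canonical uptake table for a single state (or filtered by
#'   `state`).
#' @param sigma_multiplier Acceptance multiple of the propagated SD
#'   (default 5).
#' @param state If the table holds several states, which one to process.
#' @return A tibble with one row per qualifying pair per timepoint:
#'   `region_start`, `region_end`, parent spans, `exposure_s`, `uptake_Da`
#'   (may be negative for noisy pairs), `sd_Da`, `accepted`. The overhang's
#'   own first residue is *not* re-excluded: the subtraction already
#'   removes the shared prefix's contribution (recorded in the
#'   `convention_note` attribute).
#' @export
subtract_overlaps <- function(table, sigma_multiplier = 5, state = NULL) {
  validate_uptake_table(table, check_timepoints = FALSE)
  if (!is.null(state)) table <- table[table$state == state, ]
  if (dplyr::n_distinct(table$state) > 1) {
    abort("table holds multiple states; pass `state` to select one")
  }
  peps <- dplyr::distinct(table, .data$start, .data$end)
  out <- list()
  for (i in seq_len(nrow(peps))) {
    for (j in seq_len(nrow(peps))) {
      li <- peps[i, ]; sj <- peps[j, ]  # candidate long / short
      strictly_contains <- li$start <= sj$start && li$end >= sj$end &&
        (li$end - li$start) > (sj$end - sj$start)
      if (!strictly_contains) next
      shared_start <- li$start == sj$start
      shared_end <- li$end == sj$end
      if (shared_start == shared_end) next  # need exactly one shared endpoint
      region <- if (shared_start) c(sj$end + 1L, li$end) else c(li$start, sj$start - 1L)
      rows_l <- table[table$start == li$start & table$end == li$end, ]
      rows_s <- table[table$start == sj$start & table$end == sj$end, ]
      joined <- dplyr::inner_join(
        rows_l[c("exposure_s", "uptake_Da", "sd_Da")],
        rows_s[c("exposure_s", "uptake_Da", "sd_Da")],
        by = "exposure_s", suffix = c("_long", "_short")
      )
      if (nrow(joined) == 0) next
      diff <- joined$uptake_Da_long - joined$uptake_Da_short
      sdd <- sqrt(joined$sd_Da_long^2 + joined$sd_Da_short^2)
      out[[length(out) + 1]] <- tibble(
        region_start = region[1], region_end = region[2],
        long_start = li$start, long_end = li$end,
        short_start = sj$start, short_end = sj$end,
        exposure_s = joined$exposure_s,
        uptake_Da = diff, sd_Da = sdd,
        accepted = abs(diff) > sigma_multiplier * sdd
      )
    }
  }
  res <- if (length(out) == 0) {
    tibble(
      region_start = integer(), region_end = integer(),
      long_start = integer(), long_end = integer(),
      short_start = integer(), short_end = integer(),
      exposure_s = numeric(), uptake_Da = numeric(), sd_Da = numeric(),
      accepted = logical()
    )
  } else {
    dplyr::bind_rows(out) |>
      dplyr::arrange(.data$region_start, .data$region_end, .data$exposure_s)
  }
  attr(res, "sigma_multiplier") <- sigma_multiplier
  attr(res, "convention_note") <-
    "overhang uptake = D(long) - D(short); no additional first-residue exclusion applied"
  res
}
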
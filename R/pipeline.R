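## Stage wrapper: any failure inside a pipeline stage is re-raised with the
## stage name prefixed, so a driver failure always names the failing stage.
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0(stage, ": ", conditionMessage(e)))
  })
}

#' Differential HDX-MS workflow: read, correct, fit, subtract, classify
#'
#' Runs the full experimental analysis in one call: validation of the free
#' and bound state tables, back-exchange correction against a template
#' peptide, single-exponential fitting of every peptide in both states,
#' overlapping-peptide subtraction per state, maximum-uptake differencing,
#' and significance classification. Every tunable that the analysis
#' depends on is echoed in the returned `config` so a run is reproducible
#' from its own report.
#'
#' @param table Canonical uptake table holding both states (e.g. from
#'   [read_uptake_table()] or [simulate_uptake()]), or the free-state
#'   table when `bound` is supplied separately.
#' @param bound Optional bound-state table, when not combined in `table`.
#' @param free_state,bound_state State labels (defaults `"free"`,
#'   `"bound"`).
#' @param template Template peptide for back-exchange correction
#'   (`c(start, end)`); `NULL` picks the peptide closest to full exchange;
#'   `NA` skips correction (for already-corrected or simulated loss-free
#'   tables).
#' @param sigma_multiplier Overlap-subtraction acceptance multiple.
#' @param min_delta,m Significance thresholds ([classify_significance()]).
#' @param convention Exchanging-amide convention.
#' @param structure Optional PDB (path or `bio3d` object): significant
#'   calls are painted onto its B-factors.
#' @param map_pdb_path Output path for the painted PDB (required when
#'   `structure` is given).
#' @return A list of class `hdx_differential_run`: `config`,
#'   `backexchange` (or `NULL`), `fits`, `diffs` (classified calls),
#'   `overhangs` (per state), `residue_map`.
#' @export
run_differential <- function(table, bound = NULL,
                             free_state = "free", bound_state = "bound",
                             template = NULL, sigma_multiplier = 5,
                             min_delta = 0.5, m = 2,
                             convention = c("skip_first", "skip_first_two"),
                             structure = NULL, map_pdb_path = NULL) {
  convention <- match.arg(convention)
  config <- list(
    free_state = free_state, bound_state = bound_state,
    template = template, sigma_multiplier = sigma_multiplier,
    min_delta = min_delta, m = m, convention = convention
  )
  combined <- with_stage("read", {
    if (!is.null(bound)) {
      validate_uptake_table(table, check_timepoints = FALSE)
      validate_uptake_table(bound, check_timepoints = FALSE)
      dplyr::bind_rows(table, bound)
    } else {
      validate_uptake_table(table, check_timepoints = FALSE)
      table
    }
  })
  for (st in c(free_state, bound_state)) {
    if (!st %in% combined$state) {
      abort(paste0("fit: state not found: ", st))
    }
  }
  skip_correction <- length(template) == 1 && is.na(template)
  be <- NULL
  corrected <- combined
  if (!skip_correction) {
    be <- with_stage("correct",
      correct_backexchange(combined, template = template,
                           convention = convention))
    corrected <- be$corrected
  }
  fits <- with_stage("fit", fit_uptake(corrected, convention = convention))
  overhangs <- with_stage("subtract", {
    purrr::map(
      setNames(c(free_state, bound_state), c(free_state, bound_state)),
      function(st) subtract_overlaps(corrected, sigma_multiplier, state = st)
    )
  })
  diffs <- with_stage("diff",
    diff_uptake(fits, free = free_state, bound = bound_state))
  calls <- with_stage("classify",
    classify_significance(diffs, min_delta = min_delta, m = m))
  rmap <- residue_map_from_calls(calls)
  if (!is.null(structure)) {
    if (is.null(map_pdb_path)) abort("map: map_pdb_path required with structure")
    with_stage("map",
      write_residue_map_pdb(structure, rmap, map_pdb_path))
    config$map_pdb_path <- map_pdb_path
  }
  structure(
    list(config = config, backexchange = be, fits = fits,
         diffs = calls, overhangs = overhangs, residue_map = rmap),
    class = "hdx_differential_run"
  )
}

#' Per-residue differential map from classified calls
#'
#' Residue-level summary for structure painting: each residue covered by
#' at least one significantly different peptide gets the mean
#' \eqn{\Delta D} of the significant peptides covering it; residues
#' covered only by non-significant peptides are omitted (they will carry
#' the sentinel B-factor when painted).
#'
#' @param calls Classified `hdx_diffs` table.
#' @return A tibble (`resno`, `value`) suitable for
#'   [write_residue_map_pdb()].
#' @export
residue_map_from_calls <- function(calls) {
  sig <- calls[calls$class != "not_significant", ]
  if (nrow(sig) == 0) return(tibble(resno = integer(), value = numeric()))
  purrr::pmap_dfr(sig[c("start", "end", "delta_D")],
                  function(start, end, delta_D) {
                    tibble(resno = seq.int(start, end), value = delta_D)
                  }) |>
    dplyr::group_by(.data$resno) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
}

#' @export
print.hdx_differential_run <- function(x, ...) {
  n_sig <- sum(x$diffs$class != "not_significant")
  cat("<hdx_differential_run> ", nrow(x$diffs), " peptides, ",
      n_sig, " significant call(s)\n", sep = "")
  if (!is.null(x$backexchange)) {
    cat("  back-exchange fraction: ", signif(x$backexchange$be_frac, 4), "\n",
        sep = "")
  }
  invisible(x)
}

#' Structure/MD prediction workflow: hydrogen bonds to predicted uptake
#'
#' Runs the prediction half of the pipeline: classify amide hydrogen bonds
#' (or accept a precomputed series), reduce to closed fractions and
#' protection factors, compute intrinsic rates, predict per-residue
#' deuteration, aggregate to a predicted peptide uptake table, and — when
#' an experimental table is supplied — correlate predicted against
#' experimental uptake at the longest exposure.
#'
#' @param series A hydrogen-bond series tibble ([classify_hbonds()],
#'   [read_hbond_flags()] or [generate_hbond_series()]), or a path to a
#'   flag CSV, or a `bio3d` structure / PDB path to classify directly.
#' @param sequence Full-protein sequence.
#' @param map Peptide map (`start`, `end`); defaults to the peptides of
#'   `experimental` when given.
#' @param params [logistic_params()]; `NULL` triggers calibration against
#'   `experimental` ([calibrate_logistic()]).
#' @param experimental Optional experimental uptake table of one state
#'   (back-exchange corrected) for calibration/correlation.
#' @param timepoints_s Prediction exposure times.
#' @param pH_read,temperature_K Labeling conditions for intrinsic rates.
#' @param mode Closed-state observable ([compute_protection()]).
#' @param convention Exchanging-amide convention.
#' @param xyz Optional trajectory frames when `series` is a structure.
#' @return A list of class `hdx_predict_run`: `config`, `protection`,
#'   `rates`, `residue_uptake`, `predicted` (canonical table),
#'   `calibration` (or `NULL`), `correlation` (or `NULL`).
#' @export
run_predict <- function(series, sequence, map = NULL, params = NULL,
                        experimental = NULL,
                        timepoints_s = c(0, 30, 60, 120),
                        pH_read = 7.9, temperature_K = 298.15,
                        mode = c("protein_not_water", "protein_only"),
                        convention = c("skip_first", "skip_first_two"),
                        xyz = NULL) {
  mode <- match.arg(mode)
  convention <- match.arg(convention)
  series <- with_stage("hbonds", {
    if (is.character(series) && length(series) == 1) {
      if (!file.exists(series)) abort(paste0("cannot open ", series))
      if (grepl("\\.csv$", series, ignore.case = TRUE)) {
        read_hbond_flags(series)
      } else {
        classify_hbonds(series, xyz = xyz)
      }
    } else if (inherits(series, "pdb")) {
      classify_hbonds(series, xyz = xyz)
    } else {
      series
    }
  })
  if (is.null(map)) {
    if (is.null(experimental)) abort("hbonds: need a peptide map or an experimental table")
    map <- dplyr::distinct(experimental, .data$start, .data$end)
  }
  rates <- with_stage("rates",
    intrinsic_rates(sequence, pH_read = pH_read, temperature_K = temperature_K))
  calibration <- NULL
  if (is.null(params)) {
    if (is.null(experimental)) {
      abort("protection: supply logistic params or an experimental table to calibrate against")
    }
    calibration <- with_stage("calibrate",
      calibrate_logistic(experimental, series, rates, sequence,
                         mode = mode, convention = convention))
    params <- calibration$params
  }
  protection <- with_stage("protection",
    compute_protection(series, params, mode = mode))
  residue_uptake <- with_stage("predict",
    predict_residue_uptake(protection, rates, timepoints_s))
  predicted <- with_stage("aggregate",
    aggregate_to_peptides(residue_uptake, map, sequence,
                          convention = convention))
  correlation <- NULL
  if (!is.null(experimental)) {
    correlation <- with_stage("correlate", {
      t_pred <- max(predicted$exposure_s)
      t_exp <- max(experimental$exposure_s)
      joined <- dplyr::inner_join(
        predicted[predicted$exposure_s == t_pred,
                  c("start", "end", "uptake_Da")] |>
          dplyr::rename(predicted_Da = "uptake_Da"),
        experimental[experimental$exposure_s == t_exp,
                     c("start", "end", "uptake_Da")] |>
          dplyr::rename(observed_Da = "uptake_Da"),
        by = c("start", "end")
      )
      correlate_uptake(joined, x = predicted_Da, y = observed_Da)
    })
  } else {
    inform("no experimental table supplied; correlation skipped")
  }
  structure(
    list(
      config = list(
        params = params, timepoints_s = timepoints_s, pH_read = pH_read,
        temperature_K = temperature_K, mode = mode, convention = convention,
        calibrated = !is.null(calibration)
      ),
      protection = protection, rates = rates,
      residue_uptake = residue_uptake, predicted = predicted,
      calibration = calibration, correlation = correlation
    ),
    class = "hdx_predict_run"
  )
}

#' @export
print.hdx_predict_run <- function(x, ...) {
  cat("<hdx_predict_run> ", dplyr::n_distinct(x$protection$residue),
      " residues, ",
      dplyr::n_distinct(paste(x$predicted$start, x$predicted$end)),
      " peptides\n  ", sep = "")
  print(x$config$params)
  if (!is.null(x$correlation)) {
    cat("  predicted vs observed r^2 = ",
        signif(x$correlation$r_squared, 3), "\n", sep = "")
  }
  invisible(x)
}
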
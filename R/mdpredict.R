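#' Logistic protection-factor parameters
#'
#' The protection model maps the closed-state fraction \eqn{x_i} of a
#' residue's backbone amide (fraction of trajectory frames in which it is
#' hydrogen-bonded within the protein and shielded from water) to a
#' protection factor through a logistic growth function on the log scale:
#' \deqn{\ln PF_i = \frac{L}{1 + e^{-s (x_i - x_0)}}}
#' `L` is the ceiling of \eqn{\ln PF}, `x0` the midpoint occupancy and `s`
#' the steepness.
#'
#' @param L Maximum of ln PF (> 0).
#' @param x0 Midpoint, in occupancy units (in [0, 1]).
#' @param s Steepness (> 0).
#' @return An object of class `logistic_params`.
#' @export
logistic_params <- function(L, x0, s) {
  if (L <= 0) abort("L must be > 0")
  if (s <= 0) abort("s must be > 0")
  if (x0 < 0 || x0 > 1) abort("x0 must lie in [0, 1]")
  structure(list(L = L, x0 = x0, s = s), class = "logistic_params")
}

#' @export
print.logistic_params <- function(x, ...) {
  cat("<logistic_params> L =", signif(x$L, 4), " x0 =", signif(x$x0, 4),
      " s =", signif(x$s, 4), "\n")
  invisible(x)
}

#' Protection factor from closed fraction
#'
#' @param x Closed fraction(s) in [0, 1].
#' @param params A [logistic_params()] object.
#' @return PF values (>= 1; a floor of 1 is enforced — protection can slow
#'   exchange below the intrinsic rate but never catalyse it).
#' @export
logistic_pf <- function(x, params) {
  stopifnot(inherits(params, "logistic_params"))
  ln_pf <- params$L / (1 + exp(-params$s * (x - params$x0)))
  pmax(1, exp(ln_pf))
}

# geometric defaults for an amide hydrogen bond: heavy-atom distance and
# the deviation of the acceptor from the N-H axis
hbond_defaults <- list(d_cut = 3.5, theta_cut = 30)

#' Classify backbone-amide hydrogen bonds across trajectory frames
#'
#' For every non-proline backbone amide and every frame, decides whether
#' the amide is hydrogen-bonded to a protein acceptor (backbone carbonyl
#' O, side-chain O, histidine ring N) and/or to a water oxygen. The
#' criterion is a heavy-atom distance N...acceptor <= `d_cut` together
#' with an angle between the N-H bond vector and the N->acceptor vector
#' <= `theta_cut` — the convention of common trajectory hydrogen-bond
#' tools. Acceptors on the donor's own residue are excluded. Missing amide
#' hydrogens are rebuilt at ideal geometry (bisector of N-CA and
#' N-C(prev), 1.01 angstrom) unless `reconstruct_h = FALSE`, in which case
#' residues without an H are an error.
#'
#' @param structure A `bio3d` `pdb` object (or path). Multi-model PDB files
#'   read with `bio3d::read.pdb(..., multi = TRUE)` supply their frames
#'   automatically.
#' @param xyz Optional frames-by-coordinates matrix (e.g. from
#'   `bio3d::read.dcd()`); defaults to the structure's own coordinates.
#' @param d_cut,theta_cut Geometric cutoffs (angstroms, degrees).
#' @param reconstruct_h Rebuild missing amide hydrogens (default `TRUE`).
#' @return A tibble with columns `residue`, `frame`, `bonded_to_protein`,
#'   `bonded_to_water`.
#' @export
classify_hbonds <- function(structure, xyz = NULL,
                            d_cut = hbond_defaults$d_cut,
                            theta_cut = hbond_defaults$theta_cut,
                            reconstruct_h = TRUE) {
  pdb <- if (inherits(structure, "pdb")) structure else bio3d::read.pdb(structure)
  at <- pdb$atom
  xyz <- if (is.null(xyz)) pdb$xyz else xyz
  xyz <- as.matrix(xyz)
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3 * nrow(at)) {
    abort(paste0(
      "frame/topology mismatch: frames have ", ncol(xyz) / 3,
      " atoms, topology has ", nrow(at)
    ))
  }
  water_res <- c("HOH", "WAT", "TIP", "TIP3", "SPC", "SOL", "DOD")
  is_water <- at$resid %in% water_res
  water_o <- which(is_water & (at$elety %in% c("O", "OW", "OH2") |
                                 substr(at$elety, 1, 1) == "O"))
  prot <- !is_water
  acceptor_o <- which(prot & substr(at$elety, 1, 1) == "O")
  acceptor_n <- which(prot & at$resid == "HIS" & at$elety %in% c("ND1", "NE2"))
  acceptors <- c(acceptor_o, acceptor_n)

  donors <- which(prot & at$elety == "N" & at$resid != "PRO")
  # drop chain-leading residues: their N is an amine, not an amide
  res_key <- paste(at$chain, at$resno)
  donor_keep <- vapply(donors, function(i) {
    any(prot & at$elety == "C" & res_key == prev_residue_key(at, i))
  }, logical(1))
  donors <- donors[donor_keep]
  if (length(donors) == 0) abort("no backbone amide donors found")

  h_idx <- vapply(donors, function(i) {
    j <- which(res_key == res_key[i] & at$elety %in% c("H", "HN", "HT1", "1H"))
    if (length(j) > 0) j[1] else NA_integer_
  }, integer(1))
  if (anyNA(h_idx) && !reconstruct_h) {
    abort(paste0(
      "missing amide hydrogen(s) for residue(s) ",
      paste(at$resno[donors[is.na(h_idx)]], collapse = ", "),
      " and reconstruction is disabled"
    ))
  }
  ca_idx <- vapply(donors, function(i) {
    which(res_key == res_key[i] & at$elety == "CA")[1]
  }, integer(1))
  cprev_idx <- vapply(donors, function(i) {
    j <- which(prot & at$elety == "C" & res_key == prev_residue_key(at, i))
    if (length(j) > 0) j[1] else NA_integer_
  }, integer(1))

  n_frames <- nrow(xyz)
  out <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    co <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    acc_prot <- co[acceptors, , drop = FALSE]
    acc_wat <- co[water_o, , drop = FALSE]
    bp <- logical(length(donors)); bw <- logical(length(donors))
    for (d in seq_along(donors)) {
      npos <- co[donors[d], ]
      hpos <- if (!is.na(h_idx[d])) {
        co[h_idx[d], ]
      } else {
        rebuild_amide_h(npos, co[ca_idx[d], ], co[cprev_idx[d], ])
      }
      own <- res_key[acceptors] == res_key[donors[d]]
      bp[d] <- any_hbond(npos, hpos, acc_prot[!own, , drop = FALSE],
                         d_cut, theta_cut)
      bw[d] <- any_hbond(npos, hpos, acc_wat, d_cut, theta_cut)
    }
    out[[f]] <- tibble(
      residue = at$resno[donors], frame = f,
      bonded_to_protein = bp, bonded_to_water = bw
    )
  }
  dplyr::bind_rows(out)
}

prev_residue_key <- function(at, i) paste(at$chain[i], at$resno[i] - 1)

rebuild_amide_h <- function(n, ca, c_prev) {
  u1 <- n - ca; u1 <- u1 / sqrt(sum(u1^2))
  u2 <- n - c_prev; u2 <- u2 / sqrt(sum(u2^2))
  b <- u1 + u2; b <- b / sqrt(sum(b^2))
  n + 1.01 * b
}

## TRUE if any acceptor satisfies both the distance and the angular criterion
any_hbond <- function(npos, hpos, acc, d_cut, theta_cut) {
  if (nrow(acc) == 0) return(FALSE)
  dv <- sweep(acc, 2, npos)
  dist <- sqrt(rowSums(dv^2))
  near <- dist <= d_cut & dist > 1e-6
  if (!any(near)) return(FALSE)
  nh <- hpos - npos; nh <- nh / sqrt(sum(nh^2))
  cosang <- (dv[near, , drop = FALSE] %*% nh) / dist[near]
  any(cosang >= cos(theta_cut * pi / 180))
}

#' Read / write precomputed per-frame hydrogen-bond flags
#'
#' CSV interchange format (`residue,frame,protein_flag,water_flag`) that
#' decouples protection-factor analysis from trajectory formats: any
#' external hydrogen-bond tool can feed the pipeline through it.
#'
#' @param path CSV path.
#' @return `read_hbond_flags()`: a tibble with columns `residue`, `frame`,
#'   `bonded_to_protein`, `bonded_to_water`.
#' @export
read_hbond_flags <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("residue", "frame", "protein_flag", "water_flag")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    abort(paste0("flag file missing column(s): ", paste(missing, collapse = ", ")))
  }
  tibble(
    residue = as.integer(raw$residue), frame = as.integer(raw$frame),
    bonded_to_protein = as.logical(raw$protein_flag),
    bonded_to_water = as.logical(raw$water_flag)
  )
}

#' @rdname read_hbond_flags
#' @param series A hydrogen-bond series tibble.
#' @export
write_hbond_flags <- function(series, path) {
  readr::write_csv(
    tibble(
      residue = series$residue, frame = series$frame,
      protein_flag = series$bonded_to_protein,
      water_flag = series$bonded_to_water
    ),
    path, progress = FALSE
  )
  invisible(path)
}

#' Closed fractions and protection factors from a hydrogen-bond series
#'
#' Reduces a per-frame amide hydrogen-bond series to a per-residue closed
#' fraction \eqn{x_i} and converts it to a protection factor with
#' [logistic_pf()]. The default closed-state observable is
#' "hydrogen-bonded to the protein AND not to water", reflecting the dual
#' classification of the trajectory analysis; `protein_only` ignores the
#' water flag (useful for sensitivity analysis).
#'
#' @param series Tibble from [classify_hbonds()], [read_hbond_flags()] or
#'   [generate_hbond_series()].
#' @param params A [logistic_params()] object.
#' @param mode `"protein_not_water"` (default) or `"protein_only"`.
#' @return A tibble: `residue`, `n_frames`, `x`, `ln_pf`, `pf`.
#' @export
compute_protection <- function(series, params,
                               mode = c("protein_not_water", "protein_only")) {
  mode <- match.arg(mode)
  closed <- if (mode == "protein_not_water") {
    series$bonded_to_protein & !series$bonded_to_water
  } else {
    series$bonded_to_protein
  }
  prof <- tibble(residue = series$residue, closed = closed) |>
    dplyr::group_by(.data$residue) |>
    dplyr::summarise(
      n_frames = dplyr::n(), x = mean(.data$closed), .groups = "drop"
    )
  if (any(prof$n_frames < 100)) {
    warn("fewer than 100 frames for some residues; closed fractions are noisy")
  }
  prof$pf <- logistic_pf(prof$x, params)
  prof$ln_pf <- log(prof$pf)
  prof[c("residue", "n_frames", "x", "ln_pf", "pf")]
}

#' Predict per-residue deuteration from protection factors
#'
#' EX2-limit deuteration: \eqn{D_i(t) = 1 - \exp(-k_{int,i}\, t / PF_i)}.
#' Non-exchanging positions (residue 1, prolines) emit 0.
#'
#' @param profile Protection profile ([compute_protection()]); residues
#'   missing from it are treated as unprotected (PF = 1).
#' @param rates Intrinsic rates ([intrinsic_rates()]).
#' @param timepoints_s Exposure times in seconds.
#' @return A tibble: `residue`, `exposure_s`, `D` (deuterons, in [0, 1]).
#' @export
predict_residue_uptake <- function(profile, rates, timepoints_s) {
  merged <- rates |>
    dplyr::left_join(profile[c("residue", "pf")], by = "residue") |>
    dplyr::mutate(pf = dplyr::coalesce(.data$pf, 1))
  out <- tidyr::crossing(merged, exposure_s = as.numeric(timepoints_s)) |>
    dplyr::mutate(
      D = ifelse(
        .data$exchanging,
        1 - exp(-.data$k_int_per_min * (.data$exposure_s / 60) / .data$pf),
        0
      )
    ) |>
    dplyr::select("residue", "exposure_s", "D") |>
    dplyr::arrange(.data$residue, .data$exposure_s)
  out
}

#' Aggregate per-residue deuteration to a predicted peptide uptake table
#'
#' Sums predicted per-residue deuteration over each peptide's exchanging
#' residues (same counting convention as the experimental maximum-uptake
#' analysis), producing a canonical uptake table directly comparable with
#' experimental tables.
#'
#' @param residue_uptake Tibble from [predict_residue_uptake()].
#' @param map Peptide map (`start`, `end`).
#' @param sequence Full-protein sequence (needed for the proline/first
#'   residue exclusions and peptide sequences).
#' @param convention Passed to the exchanging-residue rule.
#' @param protein,state Identifiers written into the table.
#' @return A canonical uptake tibble (`sd_Da` 0, `n_reps` 1).
#' @export
aggregate_to_peptides <- function(residue_uptake, map, sequence,
                                  convention = c("skip_first", "skip_first_two"),
                                  protein = "predicted", state = "predicted") {
  convention <- match.arg(convention)
  skip <- if (convention == "skip_first") 1L else 2L
  n <- nchar(sequence)
  if (any(map$start < 1 | map$end > n)) abort("peptide map outside sequence range")
  tps <- sort(unique(residue_uptake$exposure_s))
  d_wide <- tidyr::pivot_wider(residue_uptake, names_from = "exposure_s",
                               values_from = "D")
  rows <- purrr::pmap_dfr(map[c("start", "end")], function(start, end) {
    idx <- residue_indices_for_uptake(start, end, sequence, skip)
    sub <- d_wide[d_wide$residue %in% idx, , drop = FALSE]
    tibble(
      protein = protein, state = state,
      start = as.integer(start), end = as.integer(end),
      sequence = substr(sequence, start, end),
      exposure_s = tps,
      uptake_Da = vapply(as.character(tps), function(cn) sum(sub[[cn]]),
                         numeric(1), USE.NAMES = FALSE),
      sd_Da = 0, n_reps = 1L
    )
  })
  validate_uptake_table(rows, check_timepoints = FALSE)
  set_corrected(rows, TRUE)  # predictions carry no back-exchange loss
}

#' Calibrate the logistic protection model against experimental uptake
#'
#' Finds the logistic parameters (L, x0, s) whose predicted peptide uptake
#' best matches an experimental (back-exchange corrected) table, by
#' sum-of-squares over all nonzero timepoints (`target = "curves"`,
#' default) or over the largest timepoint only, as a maximum-uptake proxy
#' (`target = "max_uptake"`). A deterministic coarse grid search is refined
#' with bounded L-BFGS-B; bounds are L in (0, ln 1e9], s in (0, 100],
#' x0 in [0, 1].
#'
#' @param experimental Canonical uptake table of one state.
#' @param series Hydrogen-bond series covering the protein.
#' @param rates Intrinsic rates for the full sequence.
#' @param sequence Full-protein sequence.
#' @param mode Closed-state observable, see [compute_protection()].
#' @param target `"curves"` or `"max_uptake"`.
#' @param convention Exchanging-residue convention.
#' @param grid_n Grid points per parameter for the coarse search.
#' @return A list of class `hdx_logistic_fit`: `params`
#'   ([logistic_params()]), `sse`, `n_peptides`, `comparison` (tibble of
#'   experimental vs predicted uptake at the optimum).
#' @export
calibrate_logistic <- function(experimental, series, rates, sequence,
                               mode = c("protein_not_water", "protein_only"),
                               target = c("curves", "max_uptake"),
                               convention = c("skip_first", "skip_first_two"),
                               grid_n = 9) {
  mode <- match.arg(mode)
  target <- match.arg(target)
  convention <- match.arg(convention)
  validate_uptake_table(experimental, check_timepoints = FALSE)
  map <- dplyr::distinct(experimental, .data$start, .data$end)
  if (nrow(map) < 5) {
    abort("calibration needs at least 5 peptides with experimental uptake")
  }
  # occupancy is independent of the logistic parameters: compute once
  prof0 <- suppressWarnings(
    compute_protection(series, logistic_params(1, 0.5, 1), mode = mode)
  )
  x_by_res <- setNames(prof0$x, prof0$residue)
  skip <- if (convention == "skip_first") 1L else 2L
  exp_rows <- experimental[experimental$exposure_s > 0, ]
  if (target == "max_uptake") {
    exp_rows <- exp_rows |>
      dplyr::group_by(.data$start, .data$end) |>
      dplyr::filter(.data$exposure_s == max(.data$exposure_s)) |>
      dplyr::ungroup()
  }
  # per-peptide residue bookkeeping, computed once
  pep_idx <- purrr::pmap(map[c("start", "end")], function(start, end) {
    idx <- residue_indices_for_uptake(start, end, sequence, skip)
    list(
      idx = idx,
      k = rates$k_int_per_min[match(idx, rates$residue)],
      x = unname(x_by_res[as.character(idx)])
    )
  })
  names(pep_idx) <- peptide_id(map$start, map$end)
  exp_rows$pep <- peptide_id(exp_rows$start, exp_rows$end)

  sse_fun <- function(par) {
    params <- logistic_params(par[1], par[3], par[2])
    pred <- vapply(seq_len(nrow(exp_rows)), function(r) {
      pi <- pep_idx[[exp_rows$pep[r]]]
      pf <- logistic_pf(pi$x, params)
      sum(1 - exp(-pi$k * (exp_rows$exposure_s[r] / 60) / pf), na.rm = TRUE)
    }, numeric(1))
    sum((pred - exp_rows$uptake_Da)^2)
  }

  L_grid <- seq(0.5, log(1e9), length.out = grid_n)
  s_grid <- c(1, 2, 5, 10, 20, 50, 100)
  x0_grid <- seq(0, 1, length.out = grid_n)
  grid <- expand.grid(L = L_grid, s = s_grid, x0 = x0_grid)
  sse_grid <- apply(grid, 1, sse_fun)
  if (diff(range(sse_grid)) < 1e-12 * (1 + max(sse_grid))) {
    warn(paste0(
      "flat SSE surface over the search grid (range ",
      signif(diff(range(sse_grid)), 3), "); parameters are not identifiable"
    ))
  }
  # refine from the best few grid points: the SSE valley can be shallow
  # along an (L, x0) trade-off, and a single local start may stall in it
  starts <- order(sse_grid)[1:3]
  cands <- lapply(starts, function(i) {
    optim(as.numeric(grid[i, ]), sse_fun, method = "L-BFGS-B",
          lower = c(1e-6, 1e-3, 0), upper = c(log(1e9), 100, 1))
  })
  vals <- vapply(cands, `[[`, numeric(1), "value")
  par <- if (min(vals) <= min(sse_grid)) {
    cands[[which.min(vals)]]$par
  } else {
    as.numeric(grid[starts[1], ])
  }
  params <- logistic_params(par[1], par[3], par[2])
  pred_final <- vapply(seq_len(nrow(exp_rows)), function(r) {
    pi <- pep_idx[[exp_rows$pep[r]]]
    pf <- logistic_pf(pi$x, params)
    sum(1 - exp(-pi$k * (exp_rows$exposure_s[r] / 60) / pf), na.rm = TRUE)
  }, numeric(1))
  structure(
    list(
      params = params,
      sse = min(c(vals, sse_grid)),
      n_peptides = nrow(map),
      target = target,
      comparison = tibble(
        start = exp_rows$start, end = exp_rows$end,
        exposure_s = exp_rows$exposure_s,
        observed = exp_rows$uptake_Da, predicted = pred_final
      )
    ),
    class = "hdx_logistic_fit"
  )
}

#' @export
print.hdx_logistic_fit <- function(x, ...) {
  cat("<hdx_logistic_fit> ", x$n_peptides, " peptides, target = ", x$target,
      ", SSE = ", signif(x$sse, 4), "\n  ", sep = "")
  print(x$params)
  invisible(x)
}

#' @describeIn calibrate_logistic Parameters as a one-row tibble.
#' @param x An `hdx_logistic_fit`.
#' @param ... Unused.
#' @export
tidy.hdx_logistic_fit <- function(x, ...) {
  tibble(term = c("L", "x0", "s"),
         estimate = c(x$params$L, x$params$x0, x$params$s))
}

#' @describeIn calibrate_logistic Fit summary (SSE, r-squared of observed
#'   vs predicted).
#' @export
glance.hdx_logistic_fit <- function(x, ...) {
  tibble(
    n_peptides = x$n_peptides,
    sse = x$sse,
    r.squared = cor(x$comparison$observed, x$comparison$predicted)^2
  )
}
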
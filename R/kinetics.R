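#' Fit single-exponential uptake kinetics per peptide
#'
#' Fits \eqn{D(t) = A (1 - e^{-k t})} to every peptide time course in the
#' table by weighted least squares (weights \eqn{1/\sigma^2} where the
#' replicate SD is positive, unit weight otherwise), with bounds
#' \eqn{A \in [0, 1.2 N_{exch}]} and \eqn{k \in (0, 10]} s\eqn{^{-1}},
#' initialized at the maximum observed uptake and the reciprocal median
#' nonzero timepoint. `A` is the maximum (plateau) uptake in deuterons —
#' the unit of differential comparison downstream — and `k_obs` the
#' observed rate.
#'
#' When every point carries a positive replicate SD the parameter
#' covariance is computed from the supplied uncertainties directly
#' (absolute-sigma convention, \eqn{(J^T W J)^{-1}}); otherwise it falls
#' back to the residual-variance estimate of the fitter. The reported
#' `sd_A` is then widened to the profile-likelihood 1-sigma half-width:
#' short labeling schedules leave `(A, k)` weakly identified for slow
#' exchangers, where the local linearization severely understates how far
#' the plateau estimate can wander. Curves whose
#' kinetics are unresolved on the schedule (\eqn{k\, t_{max} < 0.2}) are
#' flagged `"plateau_not_reached"` and `A` is then a lower bound;
#' non-convergent curves are flagged and reported with the last-timepoint
#' uptake and an unreliable covariance.
#'
#' Curves on which the Levenberg-Marquardt step is degenerate at the
#' starting values (saturated by the first timepoint) fall back to a
#' profile fit: `A` has a closed weighted-least-squares form at fixed `k`,
#' and the profiled SSE is minimised over a dense `k` grid.
#'
#' @param table Canonical uptake table (typically back-exchange corrected).
#' @param convention Passed to [exchangeable_amides()] for the `A` bound.
#' @return A tibble of class `hdx_fits`, one row per (protein, state,
#'   peptide): `A`, `k_obs` (s^-1), `sd_A`, `sd_k`, `cov_Ak`, `rmse`,
#'   `n_points`, `n_exch`, `flag`.
#' @export
fit_uptake <- function(table, convention = c("skip_first", "skip_first_two")) {
  convention <- match.arg(convention)
  validate_uptake_table(table, check_timepoints = FALSE)
  groups <- table |>
    dplyr::group_by(.data$protein, .data$state, .data$start, .data$end,
                    .data$sequence) |>
    dplyr::group_split()
  fits <- purrr::map_dfr(groups, function(g) {
    n_exch <- exchangeable_amides(g$sequence[1], convention)
    fit <- fit_exponential_curve(g$exposure_s, g$uptake_Da, g$sd_Da, n_exch)
    tibble(
      protein = g$protein[1], state = g$state[1],
      start = g$start[1], end = g$end[1], sequence = g$sequence[1],
      n_exch = n_exch, !!!fit
    )
  })
  structure(
    dplyr::arrange(fits, .data$state, .data$start, .data$end),
    class = c("hdx_fits", class(fits)),
    convention = convention,
    corrected = is_corrected(table)
  )
}

## Single-curve weighted fit. Returns a one-row list of fit columns.
fit_exponential_curve <- function(t, y, sd, n_exch) {
  if (length(unique(t)) < 3) abort("need at least 3 distinct timepoints")
  if (!0 %in% t) abort("time course must include the t = 0 control")
  w <- ifelse(sd > 0, 1 / sd^2, 1)
  t_max <- max(t)
  empty <- list(A = 0, k_obs = NA_real_, sd_A = NA_real_, sd_k = NA_real_,
                cov_Ak = NA_real_, rmse = 0, n_points = length(t),
                flag = "degenerate")
  if (all(y <= .Machine$double.eps)) return(empty)

  A0 <- max(y)
  k0 <- 1 / median(t[t > 0])
  A_hi <- max(1.2 * n_exch, A0)  # never box the initial value out
  dat <- data.frame(t = t, y = y, w = w)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * (1 - exp(-k * t)), data = dat,
      start = list(A = A0, k = k0), weights = w,
      lower = c(A = 0, k = 1e-9), upper = c(A = A_hi, k = 10),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14)
    ),
    error = function(e) NULL
  )
  p <- if (!is.null(fit)) {
    coef(fit)
  } else {
    # profile fallback for curves where the gradient is singular at the
    # start (typically saturated by the first timepoint): A is linear
    # given k, so profile the weighted SSE over a dense k grid
    k_grid <- 10^seq(-9, 1, length.out = 600)
    prof <- vapply(k_grid, function(k) {
      f <- 1 - exp(-k * t)
      A <- max(0, min(A_hi, sum(w * y * f) / sum(w * f^2)))
      sum(w * (y - A * f)^2)
    }, numeric(1))
    k_best <- k_grid[which.min(prof)]
    f <- 1 - exp(-k_best * t)
    c(A = max(0, min(A_hi, sum(w * y * f) / sum(w * f^2))), k = k_best)
  }
  resid <- y - p[["A"]] * (1 - exp(-p[["k"]] * t))
  # covariance: absolute-sigma when per-point SDs are all supplied
  cov <- if (all(sd > 0) || is.null(fit)) {
    J <- cbind(1 - exp(-p[["k"]] * t),
               p[["A"]] * t * exp(-p[["k"]] * t))
    jwj <- crossprod(J, J * w)
    # saturated curves leave k unidentified and jwj singular; the
    # pseudo-inverse still yields a usable variance for A
    tryCatch(solve(jwj), error = function(e) MASS::ginv(jwj))
  } else {
    tryCatch(unname(vcov(fit)), error = function(e) matrix(NA_real_, 2, 2))
  }
  flag <- if (p[["k"]] * t_max < 0.2) "plateau_not_reached" else "ok"
  sd_A <- sqrt(pmax(0, cov[1, 1]))
  if (all(sd > 0)) {
    # profile-likelihood uncertainty for A: the local linearization badly
    # understates the spread of plateau estimates when the exposure
    # schedule leaves (A, k) weakly identified, so the 1-sigma interval is
    # read off the profiled weighted SSE instead
    sd_A <- profile_sd_A(t, y, w, p[["A"]], A_hi)
  }
  list(
    A = unname(p[["A"]]), k_obs = unname(p[["k"]]), sd_A = sd_A,
    sd_k = sqrt(pmax(0, cov[2, 2])),
    cov_Ak = cov[1, 2],
    rmse = sqrt(mean(resid^2)), n_points = length(t), flag = flag
  )
}

## 1-sigma half-width of A from the profile likelihood: the smallest and
## largest A at which the k-profiled weighted SSE exceeds its minimum by 1
## (the absolute-sigma convention). Censored at the parameter box, which
## caps the reported precision rather than overstating it.
profile_sd_A <- function(t, y, w, A_hat, A_box) {
  sse_at <- function(A) {
    optimize(function(lk) {
      f <- 1 - exp(-exp(lk) * t)
      sum(w * (y - A * f)^2)
    }, interval = log(c(1e-9, 10)))$objective
  }
  target <- sse_at(A_hat) + 1
  g <- function(A) sse_at(A) - target
  upper <- if (g(A_box) < 0) A_box else {
    tryCatch(uniroot(g, c(A_hat, A_box))$root, error = function(e) A_box)
  }
  lower <- if (g(0) < 0) 0 else {
    tryCatch(uniroot(g, c(0, A_hat))$root, error = function(e) 0)
  }
  (upper - lower) / 2
}

#' Maximum-uptake differences between two states
#'
#' Pairs the fitted maximum uptakes of each peptide in two states and
#' forms \eqn{\Delta D = A_{bound} - A_{free}} with the uncertainty
#' propagated in quadrature. The result is unclassified until
#' [classify_significance()] is applied.
#'
#' @param fits An `hdx_fits` table containing both states.
#' @param free,bound State labels.
#' @return A tibble of class `hdx_diffs`: peptide columns, `A_free`,
#'   `A_bound`, `delta_D`, `sd_delta_D`, `flag_free`, `flag_bound`.
#'   Peptides present in only one state are dropped with a message.
#' @export
diff_uptake <- function(fits, free = "free", bound = "bound") {
  f <- fits[fits$state == free, ]
  b <- fits[fits$state == bound, ]
  if (nrow(f) == 0 || nrow(b) == 0) {
    abort(paste0("state not found: ", if (nrow(f) == 0) free else bound))
  }
  joined <- dplyr::inner_join(
    f |> dplyr::select("protein", "start", "end", "sequence", "n_exch",
                       A_free = "A", sd_A_free = "sd_A", flag_free = "flag"),
    b |> dplyr::select("protein", "start", "end", "sequence",
                       A_bound = "A", sd_A_bound = "sd_A", flag_bound = "flag"),
    by = c("protein", "start", "end", "sequence")
  )
  dropped <- nrow(f) + nrow(b) - 2 * nrow(joined)
  if (dropped > 0) {
    inform(paste0(dropped, " unpaired peptide fit(s) dropped"))
  }
  unreliable <- !is.finite(joined$sd_A_free) | !is.finite(joined$sd_A_bound)
  if (any(unreliable)) {
    inform(paste0(sum(unreliable),
                  " peptide(s) with unreliable fit uncertainty dropped"))
    joined <- joined[!unreliable, ]
  }
  out <- joined |>
    dplyr::mutate(
      delta_D = .data$A_bound - .data$A_free,
      sd_delta_D = sqrt(.data$sd_A_free^2 + .data$sd_A_bound^2)
    )
  structure(out, class = c("hdx_diffs", class(out)),
            states = c(free = free, bound = bound))
}

#' Classify differential uptake calls
#'
#' A peptide is called `protected` (less uptake when bound) when
#' \eqn{\Delta D \le -\max(\delta_{min}, m\,\sigma_{\Delta D})},
#' `deprotected` symmetrically, and `not_significant` otherwise: the call
#' requires both a worthwhile effect size and an excursion beyond the
#' replicate uncertainty. No multiple-testing correction is applied by
#' default; `p_adjust = "BH"` replaces the \eqn{m\sigma} criterion with a
#' Benjamini-Hochberg-adjusted two-sided z-test at `alpha`.
#'
#' @param diffs An `hdx_diffs` table from [diff_uptake()].
#' @param min_delta Minimum absolute difference in deuterons (default 0.5).
#' @param m SD multiplier (default 2).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @param alpha Significance level for the BH mode.
#' @return The table with an added `class` column (factor: protected /
#'   deprotected / not_significant); thresholds recorded as attributes.
#' @export
classify_significance <- function(diffs, min_delta = 0.5, m = 2,
                                  p_adjust = c("none", "BH"), alpha = 0.05) {
  p_adjust <- match.arg(p_adjust)
  if (any(!is.finite(diffs$sd_delta_D))) {
    abort("non-finite sd_delta_D; refit or drop flagged peptides first")
  }
  if (p_adjust == "none") {
    thr <- pmax(min_delta, m * diffs$sd_delta_D)
    cls <- dplyr::case_when(
      diffs$delta_D <= -thr ~ "protected",
      diffs$delta_D >= thr ~ "deprotected",
      TRUE ~ "not_significant"
    )
  } else {
    z <- diffs$delta_D / diffs$sd_delta_D
    padj <- stats::p.adjust(2 * stats::pnorm(-abs(z)), method = "BH")
    sig <- padj <= alpha & abs(diffs$delta_D) >= min_delta
    cls <- dplyr::case_when(
      sig & diffs$delta_D < 0 ~ "protected",
      sig & diffs$delta_D > 0 ~ "deprotected",
      TRUE ~ "not_significant"
    )
  }
  out <- diffs
  out$class <- factor(cls, levels = c("protected", "not_significant", "deprotected"))
  attr(out, "thresholds") <- list(min_delta = min_delta, m = m,
                                  p_adjust = p_adjust, alpha = alpha)
  out
}

#' @describeIn fit_uptake Broom-style per-peptide parameter table.
#' @param x An `hdx_fits` object.
#' @param ... Unused.
#' @export
tidy.hdx_fits <- function(x, ...) {
  x |>
    as_tibble() |>
    tidyr::pivot_longer(
      cols = c("A", "k_obs"), names_to = "term", values_to = "estimate"
    ) |>
    dplyr::mutate(
      std.error = ifelse(.data$term == "A", .data$sd_A, .data$sd_k)
    ) |>
    dplyr::select("protein", "state", "start", "end", "term",
                  "estimate", "std.error", "flag")
}

#' @describeIn fit_uptake One-row fit-quality summary.
#' @export
glance.hdx_fits <- function(x, ...) {
  tibble(
    n_peptides = dplyr::n_distinct(paste(x$protein, x$start, x$end)),
    n_states = dplyr::n_distinct(x$state),
    n_ok = sum(x$flag == "ok"),
    n_flagged = sum(x$flag != "ok"),
    median_rmse = median(x$rmse, na.rm = TRUE)
  )
}

#' Woods-style differential uptake plot
#'
#' Draws each peptide as a horizontal segment over its residue span at its
#' \eqn{\Delta D}, coloured by significance class, with the `min_delta`
#' band shaded.
#'
#' @param diffs A classified `hdx_diffs` table ([classify_significance()]).
#' @return A ggplot object.
#' @export
plot_woods <- function(diffs) {
  if (!"class" %in% names(diffs)) {
    abort("diffs must be classified first (classify_significance)")
  }
  thr <- attr(diffs, "thresholds")
  ggplot2::ggplot(diffs) +
    ggplot2::annotate(
      "rect", xmin = -Inf, xmax = Inf,
      ymin = -thr$min_delta, ymax = thr$min_delta,
      alpha = 0.1, fill = "grey40"
    ) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$delta_D, yend = .data$delta_D,
                   colour = .data$class),
      linewidth = 1.5
    ) +
    ggplot2::scale_colour_manual(values = c(
      protected = "#c23b22", not_significant = "grey55",
      deprotected = "#2b6cb0"
    ), drop = FALSE) +
    ggplot2::labs(
      x = "residue position",
      y = expression(Delta * D ~ "(bound - free, deuterons)"),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_uptake Uptake curves with fitted exponentials, one facet
#'   per peptide (requires the originating table via `table`).
#' @param object An `hdx_fits` object.
#' @param table The uptake table the fits came from.
#' @export
autoplot.hdx_fits <- function(object, table, ...) {
  curves <- purrr::pmap_dfr(
    object[c("protein", "state", "start", "end", "A", "k_obs")],
    function(protein, state, start, end, A, k_obs) {
      tt <- seq(0, max(table$exposure_s), length.out = 60)
      tibble(protein = protein, state = state, start = start, end = end,
             exposure_s = tt,
             uptake_Da = if (is.na(k_obs)) 0 else A * (1 - exp(-k_obs * tt)))
    }
  )
  lab <- function(start, end) paste0(start, "-", end)
  ggplot2::ggplot(
    table, ggplot2::aes(.data$exposure_s, .data$uptake_Da, colour = .data$state)
  ) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$uptake_Da - .data$sd_Da,
      ymax = .data$uptake_Da + .data$sd_Da
    ), size = 0.2) +
    ggplot2::geom_line(data = curves) +
    ggplot2::facet_wrap(~ lab(start, end), scales = "free_y") +
    ggplot2::labs(x = "exposure (s)", y = "uptake (Da)") +
    ggplot2::theme_minimal()
}
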
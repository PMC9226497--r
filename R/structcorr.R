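## Bondi van der Waals radii (angstroms) by element symbol; the working set
## for protein structures plus common hetero elements.
bondi_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
  P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
  SE = 1.90, ZN = 1.39, MG = 1.73, FE = 1.80, NA. = 2.27, K = 2.75
)

## Deterministic quasi-uniform sphere sampling: Fibonacci lattice.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

## Deterministic per-atom lattice orientation (golden-ratio sequence).
## Giving every atom its own orientation decorrelates the point-sampling
## error across atoms, so totals converge much faster than with a single
## shared lattice while staying exactly reproducible.
atom_rotation <- function(i) {
  g <- (sqrt(5) - 1) / 2
  a <- 2 * pi * ((i * g) %% 1)
  b <- acos(2 * ((i * g^2) %% 1) - 1)
  rz <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
  ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  rz %*% ry
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere over the structure by point sampling: each atom's
#' accessible sphere (radius = van der Waals radius + probe) is sampled on
#' a fixed Fibonacci lattice and a point is buried if it falls inside any
#' neighbouring atom's accessible sphere. The lattice is deterministic, so
#' results are exactly reproducible for a given `n_points`.
#'
#' @param structure A `bio3d` `pdb` object or path to a PDB file.
#' @param probe_radius Solvent probe radius in angstroms (default 1.4, a
#'   water molecule).
#' @param n_points Lattice points per atom. The default (20480) is chosen so that total SASA is stable to well under 0.1% when a structure is rigidly re-oriented against the fixed lattice; coarser lattices (e.g. 960) are faster and adequate for per-peptide comparisons.
#' @param radii Named vdW radius set by element symbol (default: Bondi).
#' @return A tibble of class `hdx_sasa`: one row per atom (`eleno`,
#'   `elety`, `resno`, `resid`, `chain`, `element`, `radius`, `sasa_A2`),
#'   with `probe_radius` and `n_points` attributes. Unknown elements are an
#'   error naming the first offending atom.
#' @export
shrake_rupley <- function(structure, probe_radius = 1.4, n_points = 20480,
                          radii = bondi_radii) {
  pdb <- if (inherits(structure, "pdb")) structure else bio3d::read.pdb(structure)
  at <- pdb$atom
  elem <- toupper(trimws(at$elesy))
  elem[is.na(elem) | elem == ""] <- substr(trimws(at$elety[is.na(elem) | elem == ""]), 1, 1)
  known <- elem %in% names(radii)
  if (!all(known)) {
    bad <- which(!known)[1]
    abort(paste0(
      "no van der Waals radius for element '", elem[bad],
      "' (atom ", at$eleno[bad], " ", at$elety[bad], ")"
    ))
  }
  r <- unname(radii[elem])
  co <- cbind(at$x, at$y, at$z)
  n_atoms <- nrow(co)
  lattice <- fibonacci_sphere(n_points)
  R <- r + probe_radius
  sasa <- numeric(n_atoms)
  d2 <- as.matrix(stats::dist(co))^2
  for (i in seq_len(n_atoms)) {
    nb <- which(d2[i, ] < (R[i] + r + probe_radius)^2 & seq_len(n_atoms) != i)
    if (length(nb) == 0) {
      sasa[i] <- 4 * pi * R[i]^2
      next
    }
    pts <- sweep((lattice %*% t(atom_rotation(i))) * R[i], 2, co[i, ], `+`)
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(exposed)) break
      dj <- sweep(pts[exposed, , drop = FALSE], 2, co[j, ])
      exposed[exposed] <- rowSums(dj^2) >= R[j]^2
    }
    sasa[i] <- 4 * pi * R[i]^2 * sum(exposed) / n_points
  }
  out <- tibble(
    eleno = at$eleno, elety = at$elety, resno = at$resno,
    resid = at$resid, chain = at$chain,
    element = elem, radius = r, sasa_A2 = sasa
  )
  structure(out, class = c("hdx_sasa", class(out)),
            probe_radius = probe_radius, n_points = n_points)
}

#' Backbone SASA summed per peptide
#'
#' Sums per-atom SASA over the named backbone atoms of each peptide's
#' residues. Amide hydrogens are included by default (exchange happens at
#' the amide H); drop `"H"` from `atoms` to exclude them. Peptides with
#' residues missing from the structure are flagged; a peptide entirely
#' absent gets `NA`.
#'
#' @param sasa An `hdx_sasa` result.
#' @param map Peptide map (`start`, `end`).
#' @param atoms Backbone atom names to sum (default N, CA, C, O, H).
#' @return A tibble: `start`, `end`, `backbone_sasa_A2`,
#'   `n_missing_residues`, `flagged`.
#' @export
backbone_peptide_sasa <- function(sasa, map,
                                  atoms = c("N", "CA", "C", "O", "H")) {
  bb <- sasa[sasa$elety %in% atoms, ]
  present <- unique(sasa$resno)
  purrr::pmap_dfr(map[c("start", "end")], function(start, end) {
    res <- seq.int(start, end)
    missing <- setdiff(res, present)
    val <- if (length(missing) == length(res)) {
      NA_real_
    } else {
      sum(bb$sasa_A2[bb$resno %in% res])
    }
    tibble(
      start = as.integer(start), end = as.integer(end),
      backbone_sasa_A2 = val,
      n_missing_residues = length(missing),
      flagged = length(missing) > 0
    )
  })
}

#' Correlate two per-peptide quantities
#'
#' Ordinary least-squares line and Pearson r-squared between two
#' per-peptide columns (e.g. experimental maximum uptake against backbone
#' SASA, or against predicted uptake), with an explicit exclusion list:
#' points are only ever removed by the caller, never automatically.
#'
#' @param data A data frame with one row per peptide.
#' @param x,y Column names (tidy-eval) to correlate.
#' @param exclude Character vector of peptide ids (`"start-end"`) to
#'   exclude, or an integer vector of row indices when the data lacks
#'   `start`/`end` columns.
#' @return An object of class `hdx_correlation`: `n`, `r`, `r_squared`,
#'   `slope`, `intercept`, `excluded`, and the point table with an
#'   `included` column.
#' @export
correlate_uptake <- function(data, x, y, exclude = NULL) {
  x_q <- rlang::enquo(x); y_q <- rlang::enquo(y)
  pts <- tibble(
    x = rlang::eval_tidy(x_q, data),
    y = rlang::eval_tidy(y_q, data)
  )
  pts$id <- if (all(c("start", "end") %in% names(data))) {
    peptide_id(data$start, data$end)
  } else {
    as.character(seq_len(nrow(data)))
  }
  pts <- pts[is.finite(pts$x) & is.finite(pts$y), ]
  pts$included <- !(pts$id %in% as.character(exclude))
  inc <- pts[pts$included, ]
  if (nrow(inc) < 3) abort("fewer than 3 included points")
  if (sd(inc$x) == 0 || sd(inc$y) == 0) {
    abort("zero variance in x or y among included points")
  }
  fit <- lm(y ~ x, data = inc)
  r <- cor(inc$x, inc$y)
  structure(
    list(
      n = nrow(inc), r = r, r_squared = r^2,
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      excluded = setdiff(pts$id, inc$id),
      points = pts,
      labels = c(x = rlang::as_label(x_q), y = rlang::as_label(y_q))
    ),
    class = "hdx_correlation"
  )
}

#' @export
print.hdx_correlation <- function(x, ...) {
  cat("<hdx_correlation> n = ", x$n, ", r^2 = ", signif(x$r_squared, 3),
      ", slope = ", signif(x$slope, 4), sep = "")
  if (length(x$excluded) > 0) {
    cat(", excluded: ", paste(x$excluded, collapse = ", "), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @describeIn correlate_uptake Regression terms as a tibble.
#' @export
tidy.hdx_correlation <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @describeIn correlate_uptake One-row summary (n, r, r-squared).
#' @export
glance.hdx_correlation <- function(x, ...) {
  tibble(n = x$n, r = x$r, r.squared = x$r_squared,
         n_excluded = length(x$excluded))
}

#' @describeIn correlate_uptake Scatter plot with the fitted line; excluded
#'   points are drawn open.
#' @param object An `hdx_correlation`.
#' @export
autoplot.hdx_correlation <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(.data$x, .data$y, shape = .data$included)) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                guide = "none") +
    ggplot2::labs(
      x = object$labels[["x"]], y = object$labels[["y"]],
      subtitle = paste0("r² = ", signif(object$r_squared, 3),
                        " (n = ", object$n, ")")
    ) +
    ggplot2::theme_minimal()
}

#' Flag correlation outliers by studentized residual
#'
#' Surfaces candidate poorly-correlated peptides: ids whose externally
#' studentized residual from the x-y regression exceeds the threshold,
#' sorted by magnitude. Candidates are only reported — removal remains an
#' explicit, caller-side decision via the `exclude` argument of
#' [correlate_uptake()].
#'
#' @inheritParams correlate_uptake
#' @param threshold Absolute studentized-residual cutoff (default 2.5).
#' @return Character vector of peptide ids (possibly empty).
#' @export
flag_outliers <- function(data, x, y, threshold = 2.5) {
  x_q <- rlang::enquo(x); y_q <- rlang::enquo(y)
  pts <- tibble(
    x = rlang::eval_tidy(x_q, data),
    y = rlang::eval_tidy(y_q, data)
  )
  pts$id <- if (all(c("start", "end") %in% names(data))) {
    peptide_id(data$start, data$end)
  } else {
    as.character(seq_len(nrow(data)))
  }
  pts <- pts[is.finite(pts$x) & is.finite(pts$y), ]
  if (nrow(pts) < 5) abort("need at least 5 points to flag outliers")
  fit <- lm(y ~ x, data = pts)
  # numerically exact fits have no residual scale to studentize against
  if (summary(fit)$sigma <= 1e-10 * (sd(pts$y) + .Machine$double.xmin)) {
    return(character(0))
  }
  st <- rstudent(fit)
  hit <- which(abs(st) > threshold)
  pts$id[hit][order(-abs(st[hit]))]
}
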
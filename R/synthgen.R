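#' Generate a ground-truth per-residue protection landscape
#'
#' Builds the "true" exchange landscape that the rest of the pipeline is
#' asked to recover: a random sequence and, for each of two states, a
#' per-residue log10 protection factor. The bound state equals the free
#' state except inside `delta_regions`, where the given log10 PF shift is
#' applied — emulating a factor that protects (positive shift) or exposes
#' (negative shift) defined regions upon binding. Residue 1 and prolines
#' carry no exchangeable amide and are flagged non-exchanging.
#'
#' @param n_residues Chain length.
#' @param delta_regions A list of `c(start, end, delta_log10_pf)` triples
#'   (or a data frame with those columns); regions must not overlap.
#' @param base_log10_pf Centre of the free-state log10 PF landscape.
#' @param spread_log10_pf Half-width of the uniform per-residue variation
#'   around `base_log10_pf` (0 for a flat landscape).
#' @param p_pro Proline frequency in the random sequence.
#' @param pH_read,temperature_K Labeling conditions attached to the truth
#'   (defaults: the pH-meter reading of a Tris labeling buffer, pH 7.9, and
#'   25 C).
#' @param seed Integer seed; the generator is pure given the seed.
#' @return An object of class `hdx_ground_truth`: a list with `sequence`,
#'   `pf` (tibble: `state`, `residue`, `aa`, `exchanging`, `log10_pf`),
#'   `pH_read`, `temperature_K`, `states`.
#' @examples
#' gt <- generate_ground_truth(50, list(c(10, 20, 1)), seed = 1)
#' @export
generate_ground_truth <- function(n_residues,
                                  delta_regions = NULL,
                                  base_log10_pf = 3.5,
                                  spread_log10_pf = 1,
                                  p_pro = 0.04,
                                  pH_read = 7.9,
                                  temperature_K = 298.15,
                                  seed) {
  if (missing(seed)) abort("a seed is required")
  regions <- normalise_regions(delta_regions)
  if (nrow(regions) > 0) {
    if (any(regions$start < 1 | regions$end > n_residues | regions$start > regions$end)) {
      abort("delta_regions outside [1, n_residues]")
    }
    covered <- unlist(Map(seq, regions$start, regions$end))
    if (anyDuplicated(covered) > 0) abort("delta_regions overlap")
  }
  withr_seed(seed, {
    non_pro <- setdiff(aa_alphabet, "P")
    aa <- sample(non_pro, n_residues, replace = TRUE)
    is_pro <- runif(n_residues) < p_pro
    is_pro[1] <- FALSE  # keep the N-terminal residue exchange-defined
    aa[is_pro] <- "P"
    free <- pmax(0, base_log10_pf +
                   runif(n_residues, -spread_log10_pf, spread_log10_pf))
  })
  bound <- free
  if (nrow(regions) > 0) {
    for (r in seq_len(nrow(regions))) {
      idx <- regions$start[r]:regions$end[r]
      bound[idx] <- pmax(0, bound[idx] + regions$delta_log10_pf[r])
    }
  }
  exchanging <- aa != "P"
  exchanging[1] <- FALSE
  pf <- dplyr::bind_rows(
    tibble(state = "free", residue = seq_len(n_residues), aa = aa,
           exchanging = exchanging, log10_pf = free),
    tibble(state = "bound", residue = seq_len(n_residues), aa = aa,
           exchanging = exchanging, log10_pf = bound)
  )
  structure(
    list(
      sequence = paste(aa, collapse = ""),
      pf = pf,
      pH_read = pH_read,
      temperature_K = temperature_K,
      states = c("free", "bound")
    ),
    class = "hdx_ground_truth"
  )
}

#' @export
print.hdx_ground_truth <- function(x, ...) {
  cat("<hdx_ground_truth> ", nchar(x$sequence), " residues, states: ",
      paste(x$states, collapse = ", "), "\n", sep = "")
  cat("  pH(read) ", x$pH_read, ", T ", x$temperature_K, " K\n", sep = "")
  invisible(x)
}

normalise_regions <- function(delta_regions) {
  if (is.null(delta_regions) || (is.list(delta_regions) && length(delta_regions) == 0)) {
    return(tibble(start = integer(), end = integer(), delta_log10_pf = numeric()))
  }
  if (is.data.frame(delta_regions)) {
    stopifnot(all(c("start", "end", "delta_log10_pf") %in% names(delta_regions)))
    return(as_tibble(delta_regions))
  }
  tibble(
    start = vapply(delta_regions, function(r) as.integer(r[1]), integer(1)),
    end = vapply(delta_regions, function(r) as.integer(r[2]), integer(1)),
    delta_log10_pf = vapply(delta_regions, function(r) as.numeric(r[3]), numeric(1))
  )
}

## run code with a local RNG state so generators are pure given the seed
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(code))
}

#' Generate a pepsin-like overlapping peptide map
#'
#' Tiles the chain with peptides of random length and overlap and then
#' guarantees at least one nested pair (same start, different end) so that
#' overlapping-peptide subtraction always has work to do — mirroring the
#' redundancy of real proteolytic maps. Full coverage is not guaranteed;
#' the achieved residue coverage is attached as an attribute.
#'
#' @param n_residues Chain length.
#' @param mean_length Mean peptide length (>= 3).
#' @param mean_overlap Mean overlap between consecutive peptides.
#' @param seed Integer seed.
#' @return A tibble of peptides (`start`, `end`) sorted by start, with
#'   attribute `coverage` (fraction of residues covered).
#' @export
generate_peptide_map <- function(n_residues, mean_length = 10,
                                 mean_overlap = 3, seed) {
  if (missing(seed)) abort("a seed is required")
  if (mean_length < 3 || mean_length > n_residues) {
    abort("mean_length must be in [3, n_residues]")
  }
  withr_seed(seed, {
    starts <- integer()
    ends <- integer()
    s <- 1L
    while (s <= n_residues - 2L) {
      len <- max(3L, min(n_residues - s + 1L, stats::rpois(1, mean_length)))
      starts <- c(starts, s)
      ends <- c(ends, s + len - 1L)
      step <- max(1L, len - stats::rpois(1, mean_overlap))
      s <- s + step
    }
    map <- tibble(start = as.integer(starts), end = as.integer(ends)) |>
      dplyr::distinct()
    # guarantee a nested pair sharing a start
    long_enough <- which(map$end - map$start + 1 >= 6)
    anchor <- if (length(long_enough) > 0) sample(long_enough, 1) else 1L
    nested <- tibble(
      start = map$start[anchor],
      end = as.integer(map$start[anchor] +
                         (map$end[anchor] - map$start[anchor]) %/% 2L)
    )
    map <- dplyr::bind_rows(map, nested) |>
      dplyr::distinct() |>
      dplyr::arrange(.data$start, .data$end)
  })
  covered <- unique(unlist(Map(seq, map$start, map$end)))
  attr(map, "coverage") <- length(covered) / n_residues
  map
}

#' Simulate peptide-level uptake tables from a ground truth
#'
#' Forward model of the labeling experiment under the EX2 limit: each
#' exchanging residue deuterates as
#' \eqn{D_i(t) = 1 - \exp(-k_{int,i}\, t / PF_i)}, peptide uptake is the sum
#' over the peptide's exchanging residues (the N-terminal residue of each
#' peptide and all prolines are excluded, matching the maximum-uptake
#' counting convention of [exchangeable_amides()]), a global back-exchange
#' loss scales every observed uptake by `1 - backexchange_frac`, and
#' replicate measurements receive independent Gaussian noise. Means and
#' standard deviations over replicates are reported per timepoint, as a
#' DynamX-style state table would.
#'
#' @param truth An `hdx_ground_truth`.
#' @param map A peptide map (tibble with `start`, `end`).
#' @param timepoints_s Exposure times in seconds; must include 0 (the
#'   nondeuterated control required downstream).
#' @param noise_sd Per-replicate measurement noise (Da).
#' @param backexchange_frac Fraction of incorporated deuterium lost to
#'   back-exchange during quench and separation, in [0, 1).
#' @param n_reps Replicates per timepoint.
#' @param convention Exchanging-residue convention, see
#'   [exchangeable_amides()].
#' @param protein Protein identifier written into the table.
#' @param seed Integer seed.
#' @return An uncorrected canonical uptake tibble covering both states.
#' @export
simulate_uptake <- function(truth, map, timepoints_s = c(0, 30, 60, 120),
                            noise_sd = 0.1, backexchange_frac = 0,
                            n_reps = 3,
                            convention = c("skip_first", "skip_first_two"),
                            protein = "synthetic", seed) {
  if (missing(seed)) abort("a seed is required")
  if (!0 %in% timepoints_s) abort("timepoints must include 0 (nondeuterated control)")
  if (backexchange_frac < 0 || backexchange_frac >= 1) {
    abort("backexchange_frac must be in [0, 1)")
  }
  convention <- match.arg(convention)
  stopifnot(inherits(truth, "hdx_ground_truth"))
  n <- nchar(truth$sequence)
  if (any(map$start < 1 | map$end > n)) abort("peptide map outside sequence range")
  rates <- intrinsic_rates(truth$sequence, truth$pH_read, truth$temperature_K)
  seqs <- substring(truth$sequence, map$start, map$end)
  skip <- if (convention == "skip_first") 1L else 2L

  rows <- list()
  withr_seed(seed, {
    for (st in truth$states) {
      pf <- 10^truth$pf$log10_pf[truth$pf$state == st]
      for (p in seq_len(nrow(map))) {
        res_idx <- residue_indices_for_uptake(map$start[p], map$end[p], truth$sequence, skip)
        true_curve <- vapply(timepoints_s, function(t) {
          sum(1 - exp(-rates$k_int_per_min[res_idx] * (t / 60) / pf[res_idx]))
        }, numeric(1)) * (1 - backexchange_frac)
        reps <- matrix(
          rep(true_curve, each = n_reps) +
            if (noise_sd > 0) rnorm(n_reps * length(true_curve), 0, noise_sd) else 0,
          nrow = n_reps
        )
        rows[[length(rows) + 1]] <- tibble(
          protein = protein,
          state = st,
          start = as.integer(map$start[p]),
          end = as.integer(map$end[p]),
          sequence = seqs[p],
          exposure_s = as.numeric(timepoints_s),
          uptake_Da = pmax(0, colMeans(reps)),
          sd_Da = if (noise_sd > 0) apply(reps, 2, sd) else 0,
          n_reps = as.integer(n_reps)
        )
      }
    }
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$state, .data$start, .data$end, .data$exposure_s)
  validate_uptake_table(out)
  set_corrected(out, FALSE)
}

## residues of peptide [start, end] that contribute observable deuterium:
## drop the first `skip` positions and every proline
residue_indices_for_uptake <- function(start, end, sequence, skip = 1L) {
  idx <- seq.int(start, end)
  if (skip > 0) idx <- idx[-seq_len(min(skip, length(idx)))]
  aa <- strsplit(substr(sequence, start, end), "")[[1]]
  keep_aa <- aa[-seq_len(min(skip, length(aa)))]
  idx[keep_aa != "P"]
}

#' Generate Bernoulli per-frame amide hydrogen-bond series
#'
#' Emulates the per-frame observable of a trajectory hydrogen-bond
#' analysis: for each residue, frames are independently "closed"
#' (amide hydrogen-bonded to protein, not to water) with the given
#' probability, otherwise "open" (hydrogen-bonded to water).
#'
#' @param closed_fractions Named numeric vector (names = residue numbers)
#'   or data frame with columns `residue`, `fraction`; fractions in [0, 1].
#' @param n_frames Frames per residue.
#' @param seed Integer seed.
#' @return A tibble with columns `residue`, `frame`, `bonded_to_protein`,
#'   `bonded_to_water`.
#' @export
generate_hbond_series <- function(closed_fractions, n_frames, seed) {
  if (missing(seed)) abort("a seed is required")
  cf <- if (is.data.frame(closed_fractions)) {
    tibble(residue = as.integer(closed_fractions$residue),
           fraction = as.numeric(closed_fractions$fraction))
  } else {
    if (is.null(names(closed_fractions))) {
      abort("closed_fractions must be named by residue number")
    }
    tibble(residue = as.integer(names(closed_fractions)),
           fraction = as.numeric(closed_fractions))
  }
  if (any(cf$fraction < 0 | cf$fraction > 1)) abort("fractions must lie in [0, 1]")
  withr_seed(seed, {
    out <- cf |>
      dplyr::rowwise() |>
      dplyr::reframe(
        residue = .data$residue,
        frame = seq_len(n_frames),
        bonded_to_protein = runif(n_frames) < .data$fraction
      )
  })
  out$bonded_to_water <- !out$bonded_to_protein
  as_tibble(out)
}

#' Generate small synthetic PDB fixtures
#'
#' Toy structures with exactly known geometry, used to exercise the SASA
#' and hydrogen-bond machinery against closed-form expectations: either two
#' isolated atoms at a chosen separation, or an ideal poly-alanine
#' alpha-helix (phi = -57, psi = -47, ideal bond geometry) with backbone
#' N, CA, C, O, CB and amide H atoms.
#'
#' @param kind `"two_spheres"` or `"ideal_helix"`.
#' @param d Separation in angstroms (two_spheres).
#' @param n Number of residues (ideal_helix).
#' @param elements Atom elements for the two-sphere fixture (length 2).
#' @return A `bio3d` `pdb` object.
#' @export
generate_toy_structure <- function(kind = c("two_spheres", "ideal_helix"),
                                   d = 10, n = 12, elements = c("C", "C")) {
  kind <- match.arg(kind)
  atoms <- if (kind == "two_spheres") {
    tibble(
      eleno = 1:2, elety = c("CA", "CA"), resid = "ALA", chain = "A",
      resno = 1:2,
      x = c(0, d), y = 0, z = 0, elesy = elements
    )
  } else {
    ideal_helix_atoms(n)
  }
  pdb_from_atoms(atoms)
}

## Sequential NeRF placement: position d given bond c-d, angle b-c-d and
## dihedral a-b-c-d.
place_atom <- function(a, b, c, bond, angle_deg, dihedral_deg) {
  ang <- angle_deg * pi / 180
  dih <- dihedral_deg * pi / 180
  d_local <- bond * c(cos(pi - ang),
                      sin(pi - ang) * cos(dih),
                      sin(pi - ang) * sin(dih))
  bc <- (c - b); bc <- bc / sqrt(sum(bc^2))
  ab <- (b - a)
  nv <- pracma_cross(ab, bc); nv <- nv / sqrt(sum(nv^2))
  m <- cbind(bc, pracma_cross(nv, bc), nv)
  as.numeric(c + m %*% d_local)
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

ideal_helix_atoms <- function(n, phi = -57, psi = -47, omega = 180) {
  # ideal backbone geometry (angstroms / degrees)
  bl <- c(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
          n_h = 1.01, ca_cb = 1.53)
  ba <- c(n_ca_c = 111.2, ca_c_n = 116.2, c_n_ca = 121.7,
          ca_c_o = 120.8, c_n_h = 119.0, n_ca_cb = 110.5)
  N <- matrix(NA_real_, n, 3); CA <- N; C <- N; O <- N; H <- N; CB <- N
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(bl["n_ca"], 0, 0)
  ang <- ba["n_ca_c"] * pi / 180
  C[1, ] <- CA[1, ] + bl["ca_c"] * c(-cos(pi - ang), sin(pi - ang), 0)
  for (i in 2:n) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         bl["c_n"], ba["ca_c_n"], psi)
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                          bl["n_ca"], ba["c_n_ca"], omega)
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                         bl["ca_c"], ba["n_ca_c"], phi)
  }
  for (i in seq_len(n)) {
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         bl["c_o"], ba["ca_c_o"], psi + 180)
    CB[i, ] <- place_atom(C[i, ], N[i, ], CA[i, ],
                          bl["ca_cb"], ba["n_ca_cb"], -122)
    if (i > 1) {
      H[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                           bl["n_h"], ba["c_n_h"], 180)
    }
  }
  per_res <- lapply(seq_len(n), function(i) {
    nm <- c("N", "CA", "C", "O", "CB", if (i > 1) "H")
    xyz <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ], CB[i, ],
                 if (i > 1) H[i, ])
    tibble(
      elety = nm, resid = "ALA", chain = "A", resno = i,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      elesy = substr(nm, 1, 1)
    )
  })
  out <- dplyr::bind_rows(per_res)
  out$eleno <- seq_len(nrow(out))
  out
}

## Build a bio3d pdb object from an atom tibble by round-tripping formatted
## ATOM records through bio3d's own parser, guaranteeing a valid PDB.
pdb_from_atoms <- function(atoms) {
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    atoms$eleno,
    ifelse(nchar(atoms$elety) < 4, paste0(" ", atoms$elety), atoms$elety),
    atoms$resid, atoms$chain, atoms$resno,
    atoms$x, atoms$y, atoms$z, 1.00, 0.00, atoms$elesy
  )
  tf <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), tf)
  on.exit(unlink(tf))
  bio3d::read.pdb(tf)
}
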
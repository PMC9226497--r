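# Small constructed fixtures shared across test files.

# canonical uptake rows for a single peptide time course
make_curve <- function(start, end, sequence, t, uptake, sd = 0,
                       state = "free", protein = "p", n_reps = 3L) {
  tibble::tibble(
    protein = protein, state = state,
    start = as.integer(start), end = as.integer(end), sequence = sequence,
    exposure_s = as.numeric(t), uptake_Da = uptake,
    sd_Da = rep_len(sd, length(t)), n_reps = n_reps
  )
}

# exact exponential curve
exp_curve <- function(A, k, t) A * (1 - exp(-k * t))

# a two-residue protein fragment with an ideal amide H-bond geometry in
# frame 1 (N...O = 2.9 A, 5 degrees off the N-H axis) and the acceptor
# moved 6 A away in frame 2; optionally a water oxygen near the amide
hbond_fixture <- function(water_near = FALSE, d_NO = 2.9, theta = 5) {
  ang <- theta * pi / 180
  atoms <- tibble::tibble(
    eleno = 1:7,
    elety = c("N", "CA", "C", "O", "N", "H", "CA"),
    resid = "GLY", chain = "A",
    resno = c(1L, 1L, 1L, 1L, 2L, 2L, 2L),
    x = c(-3.0, -2.2, -1.2, d_NO * cos(ang), 0.0, 1.01, -0.5),
    y = c(1.5, 0.6, 0.8, d_NO * sin(ang), 0.0, 0.0, -1.35),
    z = 0,
    elesy = c("N", "C", "C", "O", "N", "H", "C")
  )
  if (water_near) {
    atoms <- dplyr::bind_rows(atoms, tibble::tibble(
      eleno = 8L, elety = "O", resid = "HOH", chain = "W", resno = 100L,
      x = 2.8, y = 0.15, z = 0, elesy = "O"
    ))
  }
  pdb <- hdxdiff:::pdb_from_atoms(atoms)
  xyz1 <- pdb$xyz
  xyz2 <- xyz1
  o_idx <- which(pdb$atom$elety == "O" & pdb$atom$resno == 1)
  xyz2[(3 * (o_idx - 1) + 1):(3 * o_idx)] <- c(6.0, 0, 0)
  list(pdb = pdb, xyz = rbind(as.numeric(xyz1), as.numeric(xyz2)))
}

# seeded uniform draws without touching the ambient RNG stream
runif_seeded <- function(n, seed, min = 0.05, max = 0.95) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  runif(n, min, max)
}

# construct an hdx_ground_truth directly from known per-residue log10 PFs
truth_from_pf <- function(sequence, log10_pf_free, log10_pf_bound = NULL,
                          pH_read = 7.9, temperature_K = 298.15) {
  n <- nchar(sequence)
  aa <- strsplit(sequence, "")[[1]]
  exchanging <- aa != "P"
  exchanging[1] <- FALSE
  if (is.null(log10_pf_bound)) log10_pf_bound <- log10_pf_free
  pf <- dplyr::bind_rows(
    tibble::tibble(state = "free", residue = seq_len(n), aa = aa,
                   exchanging = exchanging, log10_pf = log10_pf_free),
    tibble::tibble(state = "bound", residue = seq_len(n), aa = aa,
                   exchanging = exchanging, log10_pf = log10_pf_bound)
  )
  structure(
    list(sequence = sequence, pf = pf, pH_read = pH_read,
         temperature_K = temperature_K, states = c("free", "bound")),
    class = "hdx_ground_truth"
  )
}
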
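test_that("logistic protection has the right limits and monotonicity", {
  p <- logistic_params(L = log(1e6), x0 = 0.5, s = 40)
  expect_equal(logistic_pf(0, p), 1, tolerance = 1e-6)
  expect_equal(log(logistic_pf(1, p)),
               log(1e6) / (1 + exp(-40 * 0.5)), tolerance = 1e-9)
  # PF nondecreasing in x for random valid parameter sets, floor of 1
  set.seed(8)
  for (i in 1:25) {
    pp <- logistic_params(runif(1, 0.1, 20), runif(1), runif(1, 0.1, 60))
    x <- seq(0, 1, length.out = 101)
    pf <- logistic_pf(x, pp)
    expect_true(all(diff(pf) >= -1e-12))
    expect_true(all(pf >= 1))
  }
  expect_error(logistic_params(-1, 0.5, 1), "L")
  expect_error(logistic_params(1, 1.5, 1), "x0")
})

test_that("constructed ideal geometry is classified frame by frame", {
  fx <- hbond_fixture()
  out <- classify_hbonds(fx$pdb, xyz = fx$xyz)
  expect_equal(nrow(out), 2)            # one donor (residue 2), two frames
  expect_equal(out$residue, c(2L, 2L))
  expect_equal(out$bonded_to_protein, c(TRUE, FALSE))
  expect_equal(out$bonded_to_water, c(FALSE, FALSE))
})

test_that("an amide surrounded only by water is water-bonded", {
  fx <- hbond_fixture(water_near = TRUE, d_NO = 6)  # protein O out of reach
  out <- classify_hbonds(fx$pdb, xyz = fx$xyz[1, , drop = FALSE])
  expect_false(out$bonded_to_protein)
  expect_true(out$bonded_to_water)
})

test_that("angular and distance cutoffs are both enforced", {
  near_but_bent <- hbond_fixture(d_NO = 2.9, theta = 60)
  out <- classify_hbonds(near_but_bent$pdb,
                         xyz = near_but_bent$xyz[1, , drop = FALSE])
  expect_false(out$bonded_to_protein)
  loose <- classify_hbonds(near_but_bent$pdb,
                           xyz = near_but_bent$xyz[1, , drop = FALSE],
                           theta_cut = 75)
  expect_true(loose$bonded_to_protein)
})

test_that("frame/topology mismatches are rejected", {
  fx <- hbond_fixture()
  expect_error(classify_hbonds(fx$pdb, xyz = fx$xyz[, 1:9]), "mismatch")
})

test_that("random systems match the all-pairs brute-force oracle", {
  set.seed(19)
  for (rep in 1:6) {
    # a jittered chain of glycines plus scattered waters
    n_res <- 6
    base <- seq(0, by = 3.2, length.out = n_res)
    atoms <- purrr::map_dfr(seq_len(n_res), function(i) {
      jitter <- function() rnorm(3, 0, 1.2)
      o <- c(base[i], 0, 0) + jitter()
      tibble::tibble(
        elety = c("N", "H", "CA", "C", "O"),
        resid = "GLY", chain = "A", resno = i,
        x = c(base[i], base[i] + 1.01, base[i] + 0.5, base[i] + 1.6, o[1]),
        y = c(0, rnorm(1, 0, 0.3), 1.2, 1.4, o[2]),
        z = c(0, rnorm(1, 0, 0.3), 0, 0.4, o[3]),
        elesy = c("N", "H", "C", "C", "O")
      )
    })
    waters <- tibble::tibble(
      elety = "O", resid = "HOH", chain = "W",
      resno = 100 + seq_len(8),
      x = runif(8, -2, max(base) + 2), y = runif(8, -3, 3), z = runif(8, -3, 3),
      elesy = "O"
    )
    atoms <- dplyr::bind_rows(atoms, waters)
    atoms$eleno <- seq_len(nrow(atoms))
    pdb <- hdxdiff:::pdb_from_atoms(atoms)
    got <- classify_hbonds(pdb)
    want <- oracle_hbonds_frame(pdb$atom)
    expect_equal(got$residue, want$residue)
    expect_equal(got$bonded_to_protein, want$bonded_to_protein)
    expect_equal(got$bonded_to_water, want$bonded_to_water)
  }
})

test_that("closed fractions and PFs follow the Bernoulli series", {
  series <- generate_hbond_series(c(`5` = 0.7), n_frames = 4000, seed = 23)
  p <- logistic_params(L = log(1e5), x0 = 0.5, s = 10)
  prof <- compute_protection(series, p)
  expect_equal(prof$x, 0.7, tolerance = 3 * sqrt(0.7 * 0.3 / 4000) / 0.7)
  expect_equal(prof$pf, logistic_pf(prof$x, p))
  short <- generate_hbond_series(c(`1` = 0.5), n_frames = 20, seed = 1)
  expect_warning(compute_protection(short, p), "100 frames")
})

test_that("protein_only mode ignores the water flag", {
  series <- tibble::tibble(
    residue = 1L, frame = 1:4,
    bonded_to_protein = c(TRUE, TRUE, FALSE, FALSE),
    bonded_to_water = c(TRUE, FALSE, TRUE, FALSE)
  )
  p <- logistic_params(2, 0.5, 5)
  expect_equal(
    suppressWarnings(compute_protection(series, p, "protein_only"))$x, 0.5)
  expect_equal(
    suppressWarnings(compute_protection(series, p, "protein_not_water"))$x, 0.25)
})

test_that("predicted deuteration obeys the EX2 limits", {
  rates <- intrinsic_rates("GLSDGEWQLV", 7.9, 298.15)
  prof1 <- tibble::tibble(residue = 1:10, pf = 1)
  d <- predict_residue_uptake(prof1, rates, c(0, 30, 120))
  expect_true(all(d$D[d$exposure_s == 0] == 0))
  # PF = 1 reproduces pure intrinsic kinetics
  i <- 4
  expect_equal(
    d$D[d$residue == i & d$exposure_s == 30],
    1 - exp(-rates$k_int_per_min[i] * 0.5), tolerance = 1e-12
  )
  # infinite protection shuts exchange off
  prof_inf <- tibble::tibble(residue = 1:10, pf = Inf)
  d_inf <- predict_residue_uptake(prof_inf, rates, c(0, 30, 120))
  expect_true(all(d_inf$D == 0))
  # non-exchanging positions emit zero always
  expect_true(all(d$D[d$residue == 1] == 0))
})

test_that("aggregation sums exchanging residues per peptide", {
  seqc <- "APPPAAAAAA"
  d <- tidyr::crossing(residue = 1:10, exposure_s = c(0, 60)) |>
    dplyr::mutate(D = ifelse(.data$exposure_s == 0, 0, 0.5))
  d$D[d$residue %in% c(1, 2, 3, 4)] <- 0  # residue 1 + prolines
  # peptide over prolines only
  pred <- aggregate_to_peptides(d, tibble::tibble(start = 1L, end = 4L), seqc)
  expect_true(all(pred$uptake_Da == 0))
  # uniform 0.5 over 6 exchanging residues (peptide 4-10: skip 4, P none after)
  pred2 <- aggregate_to_peptides(d, tibble::tibble(start = 4L, end = 10L), seqc)
  expect_equal(pred2$uptake_Da[pred2$exposure_s == 60], 3.0)
})

test_that("prediction and simulation agree through the shared ground truth", {
  # closed fractions -> empirical PFs -> a ground truth with those PFs:
  # the forward simulator and the predictor must then agree exactly
  seqc <- "GLSDGEWQLVLNVWGKVEAD"
  fractions <- setNames(seq(0.05, 0.95, length.out = 20), 1:20)
  series <- generate_hbond_series(fractions, n_frames = 400, seed = 37)
  params <- logistic_params(L = log(1e4), x0 = 0.6, s = 12)
  prof <- compute_protection(series, params)
  truth <- truth_from_pf(seqc, log10(prof$pf))
  map <- tibble::tibble(start = c(1L, 3L, 8L), end = c(10L, 12L, 20L))
  sim <- simulate_uptake(truth, map, noise_sd = 0, seed = 1)
  rates <- intrinsic_rates(seqc, truth$pH_read, truth$temperature_K)
  pred <- predict_residue_uptake(prof, rates, c(0, 30, 60, 120)) |>
    aggregate_to_peptides(map, seqc)
  expect_equal(pred$uptake_Da,
               sim$uptake_Da[sim$state == "free"], tolerance = 1e-12)
})

test_that("calibration recovers planted logistic parameters", {
  seqc <- "GLSDGEWQLVLNVWGKVEADIAGHGQEVLI"
  fractions <- setNames(runif_seeded(30, seed = 41), 1:30)
  series <- generate_hbond_series(fractions, n_frames = 2000, seed = 41)
  planted <- logistic_params(L = log(1e4), x0 = 0.55, s = 12)
  prof <- compute_protection(series, planted)
  truth <- truth_from_pf(seqc, log10(prof$pf))
  map <- generate_peptide_map(30, mean_length = 8, seed = 41)
  experimental <- simulate_uptake(truth, map, noise_sd = 0, seed = 41)
  experimental <- experimental[experimental$state == "free", ]
  rates <- intrinsic_rates(seqc, truth$pH_read, truth$temperature_K)
  fit <- calibrate_logistic(experimental, series, rates, seqc)
  expect_equal(fit$params$L, planted$L, tolerance = 0.10)
  expect_equal(fit$params$x0, planted$x0, tolerance = 0.10)
  expect_lt(glance(fit)$sse, 0.05)
})

test_that("calibration refuses underdetermined inputs", {
  seqc <- "GLSDGEWQLV"
  series <- generate_hbond_series(setNames(rep(0.5, 10), 1:10), 200, seed = 2)
  rates <- intrinsic_rates(seqc, 7.9, 298.15)
  one_pep <- make_curve(1, 10, seqc, c(0, 30, 60), c(0, 2, 3))
  expect_error(calibrate_logistic(one_pep, series, rates, seqc),
               "at least 5 peptides")
})

test_that("hbond flag CSVs round-trip", {
  series <- generate_hbond_series(c(`1` = 0.4, `2` = 0.9), 50, seed = 3)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_hbond_flags(series, tf)
  back <- read_hbond_flags(tf)
  expect_equal(back, series, ignore_attr = TRUE)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("residue,frame,protein_flag", bad)
  expect_error(read_hbond_flags(bad), "water_flag")
})
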
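test_that("ground truth applies the planted shift inside regions only", {
  gt <- generate_ground_truth(50, list(c(10, 20, 1)), seed = 5)
  wide <- tidyr::pivot_wider(gt$pf, id_cols = c("residue", "aa"),
                             names_from = "state", values_from = "log10_pf")
  inside <- wide$residue >= 10 & wide$residue <= 20
  expect_equal(wide$bound[inside], wide$free[inside] + 1)
  expect_equal(wide$bound[!inside], wide$free[!inside])
  # a zero shift leaves the states identical
  gt0 <- generate_ground_truth(50, list(c(10, 20, 0)), seed = 5)
  expect_equal(
    gt0$pf$log10_pf[gt0$pf$state == "bound"],
    gt0$pf$log10_pf[gt0$pf$state == "free"]
  )
})

test_that("ground truth is pure in the seed and rejects bad regions", {
  a <- generate_ground_truth(40, seed = 7)
  b <- generate_ground_truth(40, seed = 7)
  c <- generate_ground_truth(40, seed = 8)
  expect_identical(a$sequence, b$sequence)
  expect_identical(a$pf, b$pf)
  expect_false(identical(a$sequence, c$sequence))
  expect_error(generate_ground_truth(30, list(c(5, 10, 1), c(8, 12, 1)), seed = 1),
               "overlap")
  expect_error(generate_ground_truth(30, list(c(0, 10, 1)), seed = 1),
               "outside")
  # non-exchanging flags: residue 1 and prolines
  expect_false(a$pf$exchanging[a$pf$residue == 1][1])
  pros <- a$pf$residue[a$pf$aa == "P"]
  expect_true(all(!a$pf$exchanging[a$pf$residue %in% pros]))
  expect_true(all(a$pf$log10_pf >= 0))
})

test_that("peptide maps stay in range, contain a nested pair, reproduce by seed", {
  for (seed in 1:10) {
    map <- generate_peptide_map(30, mean_length = 10, seed = seed)
    expect_true(all(map$start >= 1 & map$end <= 30))
    expect_true(all(map$end >= map$start + 2))
    shared_start <- any(duplicated(map$start))
    expect_true(shared_start)
  }
  expect_identical(generate_peptide_map(60, seed = 2),
                   generate_peptide_map(60, seed = 2))
  expect_true(attr(generate_peptide_map(60, seed = 2), "coverage") <= 1)
})

test_that("noise-free uptake saturates at the exchanging-residue count", {
  gt <- generate_ground_truth(30, base_log10_pf = 1, spread_log10_pf = 0, seed = 9)
  map <- generate_peptide_map(30, seed = 9)
  tbl <- simulate_uptake(gt, map, timepoints_s = c(0, 1e9), noise_sd = 0,
                         backexchange_frac = 0, seed = 9)
  at0 <- tbl[tbl$exposure_s == 0, ]
  expect_true(all(at0$uptake_Da == 0))
  at_inf <- tbl[tbl$exposure_s == 1e9, ]
  expect_equal(at_inf$uptake_Da, exchangeable_amides(at_inf$sequence),
               tolerance = 1e-10)
})

test_that("unprotected uptake equals a per-residue direct summation oracle", {
  gt <- generate_ground_truth(25, base_log10_pf = 0, spread_log10_pf = 0, seed = 13)
  map <- generate_peptide_map(25, seed = 13)
  t_s <- c(0, 5, 30, 120)
  tbl <- simulate_uptake(gt, map, timepoints_s = t_s, noise_sd = 0, seed = 13)
  k <- oracle_kint(gt$sequence, pD = gt$pH_read + 0.4,
                   temperature_K = gt$temperature_K)
  aa <- strsplit(gt$sequence, "")[[1]]
  for (p in seq_len(nrow(map))) {
    idx <- seq(map$start[p] + 1, map$end[p])
    idx <- idx[aa[idx] != "P"]
    for (t in t_s) {
      expected <- sum(1 - exp(-k[idx] * (t / 60)))
      got <- tbl$uptake_Da[tbl$state == "free" & tbl$start == map$start[p] &
                             tbl$end == map$end[p] & tbl$exposure_s == t]
      expect_equal(got, expected, tolerance = 1e-12)
    }
  }
})

test_that("simulation demands a t = 0 control and a valid loss fraction", {
  gt <- generate_ground_truth(20, seed = 1)
  map <- generate_peptide_map(20, seed = 1)
  expect_error(simulate_uptake(gt, map, timepoints_s = c(30, 60), seed = 1),
               "include 0")
  expect_error(simulate_uptake(gt, map, backexchange_frac = 1, seed = 1),
               "backexchange_frac")
})

test_that("replicate noise averages away over many replicates", {
  gt <- generate_ground_truth(20, base_log10_pf = 1, spread_log10_pf = 0, seed = 4)
  map <- tibble::tibble(start = 2L, end = 12L)
  clean <- simulate_uptake(gt, map, noise_sd = 0, seed = 4)
  noisy <- simulate_uptake(gt, map, noise_sd = 0.2, n_reps = 4000, seed = 4)
  expect_equal(noisy$uptake_Da[noisy$state == "free"],
               clean$uptake_Da[clean$state == "free"], tolerance = 0.01)
})

test_that("hbond series honour the closed fraction and the seed", {
  s1 <- generate_hbond_series(c(`1` = 1, `2` = 0), n_frames = 50, seed = 6)
  expect_true(all(s1$bonded_to_protein[s1$residue == 1]))
  expect_true(all(!s1$bonded_to_protein[s1$residue == 2]))
  expect_true(all(s1$bonded_to_water == !s1$bonded_to_protein))
  big <- generate_hbond_series(c(`7` = 0.5), n_frames = 1e5, seed = 6)
  expect_equal(mean(big$bonded_to_protein), 0.5, tolerance = 0.01)
  expect_identical(generate_hbond_series(c(`3` = 0.3), 100, seed = 1),
                   generate_hbond_series(c(`3` = 0.3), 100, seed = 1))
  expect_error(generate_hbond_series(c(`1` = 1.2), 10, seed = 1), "\\[0, 1\\]")
})

test_that("toy structures have the requested geometry and reparse cleanly", {
  two <- generate_toy_structure("two_spheres", d = 10)
  co <- cbind(two$atom$x, two$atom$y, two$atom$z)
  expect_equal(sqrt(sum((co[1, ] - co[2, ])^2)), 10)
  helix <- generate_toy_structure("ideal_helix", n = 12)
  expect_equal(length(unique(helix$atom$resno)), 12)
  ca <- helix$atom[helix$atom$elety == "CA", ]
  steps <- sqrt(diff(ca$x)^2 + diff(ca$y)^2 + diff(ca$z)^2)
  expect_true(all(abs(steps - 3.8) < 0.3))  # consecutive CA-CA distance
  # helical rise per residue close to the canonical 1.5 A
  axis_fit <- prcomp(cbind(ca$x, ca$y, ca$z))
  rise <- abs(diff(range(axis_fit$x[, 1]))) / (nrow(ca) - 1)
  expect_true(abs(rise - 1.5) < 0.2)
  tf <- withr::local_tempfile(fileext = ".pdb")
  bio3d::write.pdb(helix, file = tf)
  expect_equal(nrow(bio3d::read.pdb(tf)$atom), nrow(helix$atom))
})
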
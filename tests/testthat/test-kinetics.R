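test_that("noiseless exponential curves are recovered to 1e-6 relative", {
  t <- c(0, 30, 60, 120)
  tbl <- make_curve(1, 9, "ALKVDGEWQ", t, exp_curve(5, 0.05, t))
  fit <- fit_uptake(tbl)
  expect_equal(fit$A, 5, tolerance = 1e-6)
  expect_equal(fit$k_obs, 0.05, tolerance = 1e-6)
  expect_equal(fit$flag, "ok")
})

test_that("degenerate and under-determined inputs are handled explicitly", {
  t <- c(0, 30, 60, 120)
  zero <- make_curve(1, 9, "ALKVDGEWQ", t, rep(0, 4))
  fz <- fit_uptake(zero)
  expect_equal(fz$A, 0)
  expect_equal(fz$flag, "degenerate")
  short <- make_curve(1, 9, "ALKVDGEWQ", c(0, 30), c(0, 2))
  expect_error(fit_uptake(short), "3 distinct timepoints")
  no_zero <- make_curve(1, 9, "ALKVDGEWQ", c(30, 60, 120), c(1, 2, 3))
  expect_error(fit_uptake(no_zero), "t = 0")
})

test_that("slow exchangers are flagged as plateau-not-reached", {
  t <- c(0, 30, 60, 120)
  slow <- make_curve(1, 11, "ALKVDGEWQAA", t, exp_curve(9, 0.0005, t),
                     sd = 0.001)
  fit <- fit_uptake(slow)
  expect_equal(fit$flag, "plateau_not_reached")
})

test_that("the fit is scale-consistent: uptake in c*Da scales A, not k", {
  t <- c(0, 30, 60, 120)
  y <- exp_curve(4, 0.03, t) + c(0, 0.05, -0.04, 0.02)
  base <- fit_uptake(make_curve(1, 9, "ALKVDGEWQ", t, y, sd = 0.1))
  scaled <- fit_uptake(make_curve(1, 9, "ALKVDGEWQ", t, 1.5 * y, sd = 0.15))
  expect_equal(scaled$A, 1.5 * base$A, tolerance = 1e-6)
  expect_equal(scaled$k_obs, base$k_obs, tolerance = 1e-6)
})

test_that("the optimizer agrees with a dense grid-search oracle", {
  set.seed(42)
  t <- c(0, 15, 30, 60, 120, 240)
  for (i in 1:10) {
    A <- runif(1, 2, 9)
    k <- 10^runif(1, -2.2, -0.9)
    y <- pmax(0, exp_curve(A, k, t) + rnorm(length(t), 0, 0.05))
    tbl <- make_curve(2, 12, "ALKVDGEWQAL", t, y, sd = 0.05)
    fit <- fit_uptake(tbl)
    grid <- oracle_grid_fit(t, y, rep(0.05, length(t)),
                            A_range = c(max(y) * 0.7, max(y) * 1.4),
                            k_range = c(k / 5, k * 5))
    expect_equal(fit$A, grid$A, tolerance = max(2 * grid$dA / grid$A, 0.02))
    sse_fit <- sum((y - exp_curve(fit$A, fit$k_obs, t))^2 / 0.05^2)
    expect_lte(sse_fit, grid$sse * (1 + 1e-6))
  }
})

test_that("fit uncertainties cover the truth at the nominal rate", {
  # 100-seed version of the coverage property (the acceptance suite runs 1000)
  t <- c(0, 30, 60, 120)
  A <- 5; k <- 0.02; sd <- 0.1
  hits <- 0
  for (seed in 1:100) {
    set.seed(seed)
    y <- pmax(0, exp_curve(A, k, t) + rnorm(length(t), 0, sd))
    fit <- fit_uptake(make_curve(1, 9, "ALKVDGEWQ", t, y, sd = sd))
    hits <- hits + (abs(fit$A - A) <= 3 * fit$sd_A)
  }
  expect_gte(hits / 100, 0.95)
})

test_that("uptake differences propagate uncertainty in quadrature", {
  fits <- structure(
    dplyr::bind_rows(
      tibble::tibble(protein = "p", state = "free", start = 1L, end = 9L,
                     sequence = "ALKVDGEWQ", n_exch = 8L, A = 5.0, k_obs = 0.05,
                     sd_A = 0.1, sd_k = 0.001, cov_Ak = 0, rmse = 0,
                     n_points = 4L, flag = "ok"),
      tibble::tibble(protein = "p", state = "bound", start = 1L, end = 9L,
                     sequence = "ALKVDGEWQ", n_exch = 8L, A = 3.0, k_obs = 0.04,
                     sd_A = 0.1, sd_k = 0.001, cov_Ak = 0, rmse = 0,
                     n_points = 4L, flag = "ok")
    ),
    class = c("hdx_fits", "tbl_df", "tbl", "data.frame")
  )
  d <- diff_uptake(fits)
  expect_equal(d$delta_D, -2.0)
  expect_equal(d$sd_delta_D, sqrt(0.02), tolerance = 1e-12)
  # identical fits give a zero difference
  same <- fits
  same$A <- 5; same$sd_A <- 0.1
  expect_equal(diff_uptake(same)$delta_D, 0)
  expect_error(diff_uptake(fits, bound = "nope"), "state not found")
})

test_that("significance classification needs both effect size and precision", {
  d <- tibble::tibble(
    protein = "p", start = c(1L, 10L, 20L), end = c(9L, 18L, 28L),
    sequence = "ALKVDGEWQ", n_exch = 8L,
    A_free = c(5, 5, 5), sd_A_free = c(0.14, 0.035, 0.35),
    flag_free = "ok", A_bound = c(4.1, 4.6, 8), sd_A_bound = c(0.14, 0.035, 0.35),
    flag_bound = "ok",
    delta_D = c(-0.9, -0.4, 3.0), sd_delta_D = c(0.2, 0.05, 0.5)
  )
  cls <- classify_significance(d)
  expect_equal(as.character(cls$class),
               c("protected", "not_significant", "deprotected"))
  # the m*sd arm can outgrow min_delta
  wide <- d; wide$delta_D <- c(-0.9, -0.9, -0.9); wide$sd_delta_D <- c(0.2, 0.5, 0.2)
  cls2 <- classify_significance(wide)
  expect_equal(as.character(cls2$class)[2], "not_significant")  # 0.9 < 2*0.5
})

test_that("planted protection changes the sign of every in-region peptide", {
  gt <- generate_ground_truth(60, list(c(20, 35, 1.5)), seed = 31)
  map <- generate_peptide_map(60, seed = 31)
  tbl <- simulate_uptake(gt, map, noise_sd = 0.05, seed = 31)
  d <- diff_uptake(fit_uptake(tbl))
  in_region <- d$start >= 20 & d$end <= 35
  expect_true(any(in_region))
  expect_true(all(d$delta_D[in_region] < 0))
})

test_that("tidy and glance summarise fits in broom style", {
  t <- c(0, 30, 60, 120)
  tbl <- dplyr::bind_rows(
    make_curve(1, 9, "ALKVDGEWQ", t, exp_curve(5, 0.05, t), sd = 0.05),
    make_curve(1, 9, "ALKVDGEWQ", t, exp_curve(3, 0.02, t), sd = 0.05,
               state = "bound")
  )
  fits <- fit_uptake(tbl)
  td <- tidy(fits)
  expect_setequal(unique(td$term), c("A", "k_obs"))
  expect_equal(nrow(td), 4)
  gl <- glance(fits)
  expect_equal(gl$n_peptides, 1)
  expect_equal(gl$n_states, 2)
})
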
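test_that("TA-MSD matches closed forms on constructed trajectories", {
  # static
  tr <- make_traj(rep(2, 30), rep(-1, 30))
  msd <- compute_tamsd(tr, 0.1)
  expect_true(all(msd$msd_um2 == 0))

  # pure drift, d = 0.1 um per frame: MSD(n dt) = (n d)^2
  tr <- make_traj(0.1 * (0:29))
  msd <- compute_tamsd(tr, 0.1, max_lag = 5)
  expect_equal(msd$msd_um2, (0.1 * (1:5))^2, tolerance = 1e-12)
  expect_equal(msd$msd_um2[3], 0.09, tolerance = 1e-12)

  # oscillation x = 0,1,0,1,0
  tr <- make_traj(c(0, 1, 0, 1, 0))
  msd <- compute_tamsd(tr, 0.1, max_lag = 2, min_len = 2)
  expect_identical(msd$msd_um2, c(1, 0))
  expect_identical(msd$n_pairs, c(4L, 3L))
})

test_that("TA-MSD equals the brute-force all-pairs oracle exactly", {
  set.seed(71)
  for (rep in 1:8) {
    n <- sample(20:200, 1)
    tr <- make_traj(cumsum(rnorm(n, 0, 0.2)), cumsum(rnorm(n, 0, 0.2)))
    ml <- max(2L, floor(n / 4))
    msd <- compute_tamsd(tr, 0.1, max_lag = ml)
    orc <- oracle_tamsd(tr$frame, tr$x_um, tr$y_um, ml)
    expect_equal(msd$msd_um2, orc$msd, tolerance = 1e-12)
    expect_identical(msd$n_pairs, orc$n_pairs)
    expect_true(all(diff(msd$n_pairs) < 0))
  }
})

test_that("pairs spanning closed gaps contribute to the true frame-difference lag", {
  set.seed(72)
  for (rep in 1:5) {
    n <- 60
    tr <- make_traj(cumsum(rnorm(n, 0, 0.2)), cumsum(rnorm(n, 0, 0.2)))
    drop <- sample(2:(n - 1), 8)
    tr <- tr[-drop, ]
    msd <- compute_tamsd(tr, 0.1, max_lag = 12)
    orc <- oracle_tamsd(tr$frame, tr$x_um, tr$y_um, 12)
    expect_equal(msd$msd_um2, orc$msd, tolerance = 1e-12)
    expect_identical(msd$n_pairs, orc$n_pairs)
  }
})

test_that("short trajectories are rejected with the id in the message", {
  tr <- make_traj(1:5 / 10, id = 99L)
  expect_error(compute_tamsd(tr, 0.1, min_len = 20), "99")
})

test_that("D estimator recovers slope/4 and reports the noise intercept", {
  msd <- make_msd(4 * 0.1 * (1:10) * 0.1)
  fit <- estimate_D(msd)
  expect_equal(fit$D, 0.1, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_false(fit$flagged)

  msd <- make_msd(4 * 0.1 * (1:10) * 0.1 + 0.0036)
  fit <- estimate_D(msd)
  expect_equal(fit$D, 0.1, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.0036, tolerance = 1e-12)

  # negative slope clamps to zero and flags
  fit <- estimate_D(make_msd(c(0.4, 0.3, 0.2, 0.1, 0.05)))
  expect_identical(fit$D, 0)
  expect_true(fit$flagged)

  expect_error(estimate_D(make_msd(c(0.1, 0.2, 0.3)), n_fit = 4), "4 usable lags")
})

test_that("alpha estimator recovers power-law exponents exactly", {
  tau <- (1:10) * 0.1
  expect_equal(estimate_alpha(make_msd(0.3 * tau))$alpha, 1, tolerance = 1e-12)
  expect_equal(estimate_alpha(make_msd(0.3 * tau^2))$alpha, 2, tolerance = 1e-12)
  expect_equal(estimate_alpha(make_msd(0.3 * tau))$r2, 1, tolerance = 1e-12)
  # non-positive values are dropped; < 3 usable lags -> undefined
  out <- estimate_alpha(make_msd(c(0.1, 0, -1, 0)))
  expect_true(is.na(out$alpha))
  expect_identical(out$n_used, 1L)
})

test_that("mode classification applies thresholds with Brownian tie-break", {
  th <- alpha_thresholds(0.7, 1.3)
  expect_identical(classify_mode(c(0.3, 1.0, 1.6), th),
                   c("confined", "brownian", "directed"))
  expect_identical(classify_mode(c(0.7, 1.3), th), c("brownian", "brownian"))
  expect_true(is.na(classify_mode(NA_real_, th)))
  expect_error(alpha_thresholds(1.3, 0.7), "confined_max")
})

test_that("threshold sweep reports fractions and their grid drift", {
  sw <- threshold_sweep(rep(1, 200))
  expect_true(all(sw$table$frac_brownian == 1))
  expect_identical(unname(sw$max_change), c(0, 0, 0))

  # uniform alphas on [0, 2]: fractions vary linearly with the thresholds
  set.seed(8)
  a <- runif(20000, 0, 2)
  sw <- threshold_sweep(a)
  row <- sw$table[sw$table$confined_max == 0.5 & sw$table$directed_min == 1.5, ]
  expect_equal(row$frac_confined, 0.25, tolerance = 0.03)
  expect_equal(row$frac_brownian, 0.50, tolerance = 0.03)

  # well-separated trimodal mixture: drift < 5 points
  a <- c(rnorm(3000, 0.35, 0.05), rnorm(3000, 0.98, 0.06), rnorm(3000, 1.7, 0.05))
  sw <- threshold_sweep(a)
  expect_lt(max(sw$max_change), 0.05)

  expect_error(threshold_sweep(runif(50)), "100")
})

test_that("fit_motion assembles per-trajectory fits and accounts for excluded records", {
  spec <- population_spec(c(brownian = 1),
                          list(brownian = mode_params("brownian", 0.1)),
                          n_traj = 40, n_frames = 60, seed = 21)
  pop <- simulate_population(spec)
  # one trajectory too short to analyse
  short <- make_traj(1:10 / 10, id = 9999L)
  fits <- fit_motion(rbind(pop, short), 0.1)
  expect_identical(nrow(fits), 40L)
  expect_identical(attr(fits, "dropped_short"), 1L)
  expect_true(all(fits$D_um2_s >= 0))
  expect_true(all(fits$mode %in% c("confined", "brownian", "directed") |
                  is.na(fits$mode)))
})

test_that("(D, alpha) estimators are jointly unbiased for noiseless Brownian input", {
  # scaled-down Monte-Carlo check: median alpha in [0.95, 1.05],
  # median D within 5%
  D <- 0.18
  spec <- population_spec(c(brownian = 1),
                          list(brownian = mode_params("brownian", D, sdlog = 0)),
                          n_traj = 1500, n_frames = 100, sigma_loc = 0, seed = 13)
  fits <- fit_motion(simulate_population(spec), 0.1)
  expect_gt(median(fits$alpha), 0.95)
  expect_lt(median(fits$alpha), 1.05)
  expect_equal(median(fits$D_um2_s), D, tolerance = 0.05)
})
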
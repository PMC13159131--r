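test_that("zero diffusion and pure drift produce exact closed-form tracks", {
  tr0 <- simulate_trajectory(mode_params("brownian", 0), 20, 0.1, 0, seed = 1)
  expect_true(all(tr0$x_um == 0) && all(tr0$y_um == 0))

  trd <- simulate_trajectory(mode_params("directed", 0, v = 1, drift_heading = 0.7),
                             10, 0.1, 0, seed = 1)
  steps <- sqrt(diff(trd$x_um)^2 + diff(trd$y_um)^2)
  expect_equal(steps, rep(0.1, 9), tolerance = 1e-12)
  # collinear
  dx <- diff(trd$x_um); dy <- diff(trd$y_um)
  expect_equal(sd(atan2(dy, dx)), 0, tolerance = 1e-12)
})

test_that("invalid inputs are rejected with the offending field named", {
  expect_error(simulate_trajectory(mode_params("brownian", 0.1), 1, 0.1, 0, seed = 1),
               "n_frames")
  expect_error(simulate_trajectory(mode_params("brownian", 0.1), 10, -0.1, 0, seed = 1),
               "dt")
  expect_error(mode_params("confined", 0.1, R = -1), "R")
  expect_error(mode_params("directed", 0.1, v = 0), "v")
  expect_error(population_spec(c(brownian = 0.5, confined = 0.4),
                               list(brownian = mode_params("brownian", 0.1),
                                    confined = mode_params("confined", 0.1)),
                               10, 10), "fractions")
})

test_that("simulation is deterministic given spec and seed", {
  spec <- population_spec(c(confined = 0.4, brownian = 0.4, directed = 0.2),
                          list(confined = mode_params("confined", 0.1),
                               brownian = mode_params("brownian", 0.1),
                               directed = mode_params("directed", 0.1)),
                          n_traj = 30, n_frames = 40, seed = 11)
  a <- simulate_population(spec)
  b <- simulate_population(spec)
  expect_identical(a, b)
  spec2 <- spec; spec2$seed <- 12L
  expect_false(identical(a, simulate_population(spec2)))
})

test_that("degenerate mixture labels every trajectory with the single mode", {
  spec <- population_spec(c(brownian = 1),
                          list(brownian = mode_params("brownian", 0.05)),
                          n_traj = 100, n_frames = 5, seed = 2)
  pop <- simulate_population(spec)
  expect_identical(unique(pop$true_mode), "brownian")
  expect_identical(length(unique(pop$traj_id)), 100L)
})

test_that("empirical mode counts match requested fractions within binomial CI", {
  n <- 10000
  fr <- c(confined = 0.44, brownian = 0.32, directed = 0.24)
  spec <- population_spec(fr,
                          list(confined = mode_params("confined", 0.1),
                               brownian = mode_params("brownian", 0.1),
                               directed = mode_params("directed", 0.1)),
                          n_traj = n, n_frames = 2, seed = 31)
  pop <- simulate_population(spec)
  counts <- table(pop$true_mode[pop$frame == 0])
  for (m in names(fr)) {
    ci <- qbinom(c(0.005, 0.995), n, fr[[m]])
    expect_gte(counts[[m]], ci[1])
    expect_lte(counts[[m]], ci[2])
  }
})

test_that("Brownian ensemble MSD at lag 1 matches 4*D*dt", {
  n <- 10000; D <- 0.1; dt <- 0.1
  spec <- population_spec(c(brownian = 1),
                          list(brownian = mode_params("brownian", D, sdlog = 0)),
                          n_traj = n, n_frames = 50, dt = dt, sigma_loc = 0,
                          seed = 5)
  pop <- simulate_population(spec)
  d2 <- unlist(lapply(split(pop, pop$traj_id), function(tr)
    diff(tr$x_um)^2 + diff(tr$y_um)^2))
  expect_equal(mean(d2), 4 * D * dt, tolerance = 0.02)
})

test_that("localization noise adds the 4*sigma^2 offset to the ensemble MSD", {
  n <- 6000; D <- 0.1; dt <- 0.1; sl <- 0.05
  spec <- population_spec(c(brownian = 1),
                          list(brownian = mode_params("brownian", D, sdlog = 0)),
                          n_traj = n, n_frames = 20, dt = dt, sigma_loc = sl,
                          seed = 6)
  pop <- simulate_population(spec)
  d2 <- unlist(lapply(split(pop, pop$traj_id), function(tr)
    diff(tr$x_um)^2 + diff(tr$y_um)^2))
  expect_equal(mean(d2), 4 * D * dt + 4 * sl^2, tolerance = 0.025)
})

test_that("scale_spec scales D linearly and the tied R, v with sqrt(D)", {
  spec <- population_spec(c(confined = 0.5, directed = 0.5),
                          list(confined = mode_params("confined", 0.1),
                               directed = mode_params("directed", 0.1)),
                          10, 10)
  s2 <- scale_spec(spec, 0.78)
  expect_equal(s2$mode_params$confined$D, 0.078)
  expect_equal(s2$mode_params$confined$R,
               spec$mode_params$confined$R * sqrt(0.78))
  expect_equal(s2$mode_params$directed$v,
               spec$mode_params$directed$v * sqrt(0.78))
})

test_that("confined tracks stay within the corral (up to localization noise)", {
  p <- mode_params("confined", 0.2, R = 0.3)
  tr <- simulate_trajectory(p, 500, 0.1, 0, seed = 3)
  r <- sqrt((tr$x_um - tr$x_um[1])^2 + (tr$y_um - tr$y_um[1])^2)
  expect_lte(max(r), 0.3 + 1e-12)
})
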
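test_that("pure background frames yield no detections", {
  ms <- movie_spec(field_size = 10)
  mv <- render_movie(make_traj(numeric(0)), ms, seed = 3, n_frames = 2)
  d <- detect_spots(mv$stack[, , 1], ms$pixel_size, ms$psf_sigma)
  expect_identical(nrow(d), 0L)
  # constant image is not an error either
  expect_identical(nrow(detect_spots(matrix(5, 50, 50), 0.107)), 0L)
})

test_that("a single emitter is localized within 0.1 px at SNR ~ 10", {
  ms <- movie_spec(field_size = 8)
  pos <- c(4.0317, 3.7689)  # deliberately subpixel
  tr <- make_traj(rep(pos[1], 5), rep(pos[2], 5))
  mv <- render_movie(tr, ms, seed = 17)
  for (f in 1:5) {
    d <- detect_spots(mv$stack[, , f], ms$pixel_size, ms$psf_sigma)
    expect_identical(nrow(d), 1L)
    err_px <- sqrt((d$x_um - pos[1])^2 + (d$y_um - pos[2])^2) / ms$pixel_size
    expect_lt(err_px, 0.1)
    expect_gt(d$width_um, 0.5 * ms$psf_sigma)
    expect_lt(d$width_um, 2 * ms$psf_sigma)
  }
})

test_that("localization bias on symmetric noiseless spots is below 1e-3 px", {
  px <- 0.107; sigma <- 0.12
  for (frac in c(0, 0.3, 0.5, 0.77)) {
    x0 <- (10 + frac) * px; y0 <- (11 + frac / 2) * px
    xs <- (5:16) * px; ys <- (6:17) * px
    ex <- pnorm(xs + px, x0, sigma) - pnorm(xs, x0, sigma)
    ey <- pnorm(ys + px, y0, sigma) - pnorm(ys, y0, sigma)
    win <- 1000 * outer(ey, ex) + 5
    fit <- smtrack:::.fit_gaussian_spot(win, 5, 6, px, sigma)
    expect_lt(abs(fit$x_um - x0) / px, 1e-3)
    expect_lt(abs(fit$y_um - y0) / px, 1e-3)
  }
})

test_that("detection recall and precision reach 0.9 at the working density", {
  mv <- render_density_movie(n_frames = 3)
  ms <- mv$movie_spec
  dets <- detect_stack(mv$stack, ms$pixel_size, ms$psf_sigma)
  match_r <- 2 * ms$pixel_size
  for (f in 0:2) {
    tru <- mv$truth[mv$truth$frame == f, ]
    d <- dets[dets$frame == f, ]
    nn_t <- vapply(seq_len(nrow(tru)), function(i)
      min(sqrt((d$x_um - tru$x_um[i])^2 + (d$y_um - tru$y_um[i])^2)), 0)
    nn_d <- vapply(seq_len(nrow(d)), function(i)
      min(sqrt((tru$x_um - d$x_um[i])^2 + (tru$y_um - d$y_um[i])^2)), 0)
    expect_gte(mean(nn_t < match_r), 0.9)  # recall
    expect_gte(mean(nn_d < match_r), 0.9)  # precision
  }
})

test_that("density estimation divides mean per-frame detections by area", {
  expect_identical(estimate_density(data.frame(frame = integer(0)), 100), 0)
  one <- data.frame(frame = rep(0L, 131))
  expect_equal(estimate_density(one, 655.36), 131 / 655.36, tolerance = 1e-12)
  expect_equal(estimate_density(one, 655.36), 0.1999, tolerance = 1e-4)
  expect_error(estimate_density(one, 0), "field_area_um2")
})

test_that("detected density increases monotonically with true density", {
  ms <- movie_spec(field_size = 12.8, bleach_prob = 0)
  est <- vapply(c(0.05, 0.2, 0.5), function(dens) {
    n_emit <- round(dens * 12.8^2)
    spec <- population_spec(c(brownian = 1),
                            list(brownian = mode_params("brownian", 0.05)),
                            n_traj = n_emit, n_frames = 2, seed = 41)
    trajs <- place_in_field(simulate_population(spec), 12.8, seed = 42)
    mv <- render_movie(trajs, ms, seed = 43)
    dets <- detect_stack(mv$stack, ms$pixel_size, ms$psf_sigma)
    estimate_density(dets, (ms$n_px * ms$pixel_size)^2)
  }, 0)
  expect_true(all(diff(est) > 0))
})

test_that("intensity traces follow the emitter and flag clipped apertures", {
  # noiseless constant emitter: build expected image directly
  px <- 0.107; sigma <- 0.12; npx <- 60
  x0 <- 3.2; y0 <- 3.1
  xs <- (0:(npx - 1)) * px
  ex <- pnorm(xs + px, x0, sigma) - pnorm(xs, x0, sigma)
  ey <- pnorm(xs + px, y0, sigma) - pnorm(xs, y0, sigma)
  frame <- 800 * outer(ey, ex)
  stack <- array(rep(frame, 5), dim = c(npx, npx, 5))
  tr <- extract_trace(stack, c(x0, y0), px)
  expect_equal(tr$value, rep(tr$value[1], 5), tolerance = 1e-9)
  expect_equal(tr$value[1], 800, tolerance = 0.02)
  expect_false(attr(tr, "clipped"))

  # empty region: mean ~ 0
  tr0 <- extract_trace(stack, c(5.9, 5.9), px)
  expect_lt(abs(mean(tr0$value)), 1)

  # clipped aperture flagged
  trc <- extract_trace(stack, c(0.1, 3), px)
  expect_true(attr(trc, "clipped"))
  expect_error(extract_trace(stack, c(50, 3), px), "position")
})

test_that("a bleaching emitter's trace drops to background at the bleach frame", {
  ms <- movie_spec(field_size = 6, bleach_prob = 0.08)
  tr <- make_traj(rep(3, 60), rep(3, 60))
  mv <- render_movie(tr, ms, seed = 12)
  k <- sum(mv$truth$alive)
  expect_lt(k, 60)  # bleached within the movie
  trace <- extract_trace(mv$stack, c(3, 3), ms$pixel_size)
  expect_gt(mean(trace$value[seq_len(k)]), 700)
  expect_lt(abs(mean(trace$value[(k + 1):60])), 60)
  st <- count_bleach_steps(trace)
  expect_identical(st$n_steps, 1L)
  expect_lte(abs(st$step_frames - k), 1)
})

test_that("bleach-step counting resolves steps and controls false positives", {
  set.seed(91)
  # single synthetic step 1000 -> 0 at frame 50, SNR 10
  v <- c(rep(1000, 50), rep(0, 50)) + rnorm(100, 0, 100)
  st <- count_bleach_steps(data.frame(frame = 0:99, value = v))
  expect_identical(st$n_steps, 1L)
  expect_lte(abs(st$step_frames - 50), 1)

  # two-step staircase (two overlapping emitters)
  v2 <- c(rep(2000, 40), rep(1000, 40), rep(0, 40)) + rnorm(120, 0, 100)
  expect_identical(count_bleach_steps(data.frame(frame = 0:119, value = v2))$n_steps, 2L)

  # false-positive rate on constant-noise traces <= 5%
  fp <- vapply(1:60, function(i)
    count_bleach_steps(data.frame(frame = 0:79,
                                  value = rnorm(80, 500, 60)))$n_steps > 0, TRUE)
  expect_lte(mean(fp), 0.05)

  expect_error(count_bleach_steps(data.frame(frame = 0:5, value = rep(1, 6))),
               "10")
})
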
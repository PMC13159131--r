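# Shared helpers: independent brute-force oracles and small builders.

# Brute-force TA-MSD oracle: direct double loop over all ordered pairs,
# lags defined by true frame difference. Independent of the package's
# compiled implementation.
oracle_tamsd <- function(frame, x, y, max_lag) {
  msd <- rep(NA_real_, max_lag)
  npairs <- integer(max_lag)
  for (lag in seq_len(max_lag)) {
    s <- 0; m <- 0
    for (i in seq_along(frame)) for (j in seq_along(frame)) {
      if (frame[j] - frame[i] == lag) {
        s <- s + (x[j] - x[i])^2 + (y[j] - y[i])^2
        m <- m + 1
      }
    }
    if (m > 0) msd[lag] <- s / m
    npairs[lag] <- as.integer(m)
  }
  list(msd = msd, n_pairs = npairs)
}

make_traj <- function(x, y = NULL, frame = NULL, id = 1L) {
  n <- length(x)
  if (is.null(y)) y <- rep(0, n)
  if (is.null(frame)) frame <- seq_len(n) - 1L
  data.frame(traj_id = rep(id, n), frame = frame, x_um = x, y_um = y,
             true_mode = rep(NA_character_, n), true_D = rep(NA_real_, n))
}

# msd_curve from explicit values (for estimator unit tests)
make_msd <- function(values, dt = 0.1) {
  structure(data.frame(lag_s = seq_along(values) * dt, msd_um2 = values,
                       n_pairs = rev(seq_along(values)) + 10L),
            class = c("msd_curve", "data.frame"))
}

# mean per-ground-truth-trajectory Jaccard overlap between ground-truth and
# linked trajectories (detection sets matched by frame + position)
mean_trajectory_jaccard <- function(truth, linked, match_r) {
  gt <- split(truth, truth$traj_id)
  lk <- split(linked, linked$traj_id)
  jac <- vapply(gt, function(g) {
    best <- 0
    for (l in lk) {
      mf <- intersect(g$frame, l$frame)
      if (!length(mf)) next
      gi <- g[match(mf, g$frame), ]
      li <- l[match(mf, l$frame), ]
      shared <- sum(sqrt((gi$x_um - li$x_um)^2 + (gi$y_um - li$y_um)^2) < match_r)
      best <- max(best, shared / (nrow(g) + nrow(l) - shared))
    }
    best
  }, 0)
  mean(jac)
}

# one rendered density-QC movie shared by localization and linking tests
render_density_movie <- function(n_frames, D = 0.05, seed = 9,
                                 density = 0.2, field = 25.6) {
  ms <- movie_spec(field_size = field, bleach_prob = 0)
  n_emit <- round(density * field^2)
  spec <- population_spec(c(brownian = 1),
                          list(brownian = mode_params("brownian", D)),
                          n_traj = n_emit, n_frames = n_frames, seed = seed)
  trajs <- place_in_field(simulate_population(spec), field, seed = seed + 1)
  mv <- render_movie(trajs, ms, seed = seed + 2)
  mv$movie_spec <- ms
  mv
}
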
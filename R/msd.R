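# Time-averaged MSD, D / alpha estimation, and motion-mode classification.

#' Time-averaged mean squared displacement of one trajectory
#'
#' For each lag `n` in `1:max_lag`, averages the squared Euclidean
#' displacement over all ordered frame pairs `(i, i + n)`. Pairs spanning
#' closed gaps (missing frames) use the true frame difference and contribute
#' to the lag equal to that difference.
#'
#' @param traj data.frame with columns `frame`, `x_um`, `y_um` (one
#'   trajectory; frames strictly increasing).
#' @param dt frame interval (s).
#' @param max_lag maximum lag in frames; default `floor(n_frames / 4)`
#'   (pair-count noise control).
#' @param min_len minimum trajectory length; shorter input is rejected.
#' @return an `msd_curve`: data.frame with `lag_s`, `msd_um2`, `n_pairs`.
#'   Lags with no pairs (possible under gaps) carry `NA` values.
#' @export
compute_tamsd <- function(traj, dt, max_lag = NULL, min_len = 2L) {
  check_num(dt, "dt", positive = TRUE)
  n <- nrow(traj)
  if (n < min_len)
    stop(sprintf("trajectory %s too short (%d < %d frames)",
                 paste(unique(traj$traj_id), collapse = ","), n, min_len),
         call. = FALSE)
  f <- traj$frame
  if (is.unsorted(f, strictly = TRUE))
    stop_bad("frame", "indices must be strictly increasing")
  span <- f[n] - f[1] + 1L
  if (is.null(max_lag)) max_lag <- max(1L, floor(n / 4))
  max_lag <- check_count(max_lag, "max_lag")
  if (max_lag >= span) max_lag <- span - 1L
  if (span == n) {
    r <- .tamsd_contiguous(traj$x_um, traj$y_um, max_lag)
  } else {
    x <- rep(NA_real_, span); y <- rep(NA_real_, span)
    idx <- f - f[1] + 1L
    x[idx] <- traj$x_um; y[idx] <- traj$y_um
    r <- .tamsd_gapped(x, y, max_lag)
  }
  structure(data.frame(lag_s = seq_len(max_lag) * dt,
                       msd_um2 = r$msd, n_pairs = r$n_pairs),
            class = c("msd_curve", "data.frame"))
}

#' Diffusion coefficient from the short-lag MSD
#'
#' Ordinary least squares of MSD on lag time over the first `n_fit` lags;
#' `D = slope / 4` for 2-D motion. The intercept absorbs the constant
#' localization-noise offset `4 * sigma_loc^2`. A negative slope is clamped
#' to `D = 0` and flagged.
#'
#' @param msd an `msd_curve` from [compute_tamsd()].
#' @param n_fit number of lags in the fit window (default 4; >= 2).
#' @return list with `D` (um^2/s), `intercept` (um^2), `flagged` (logical:
#'   negative slope clamped).
#' @export
estimate_D <- function(msd, n_fit = 4L) {
  n_fit <- check_count(n_fit, "n_fit", min = 2L)
  use <- which(!is.na(msd$msd_um2))
  use <- use[seq_len(min(n_fit, length(use)))]
  if (length(use) < n_fit)
    stop(sprintf("need %d usable lags for the D fit, have %d", n_fit, length(use)),
         call. = FALSE)
  fit <- ols_fit(msd$lag_s[use], msd$msd_um2[use])
  D <- fit[["slope"]] / 4
  flagged <- D < 0
  list(D = max(D, 0), intercept = fit[["intercept"]], flagged = flagged)
}

#' Anomalous diffusion exponent from the log-log MSD
#'
#' Slope of ordinary least squares of `log(MSD)` on `log(lag)` over the lags
#' in `fit_window`, after dropping non-positive or missing MSD values. With
#' fewer than 3 usable lags the exponent is undefined (`NA`) and the
#' trajectory is excluded from mode classification downstream.
#'
#' @param msd an `msd_curve`.
#' @param fit_window integer lags to use (default `1:10`, capped at the
#'   available lags).
#' @return list with `alpha`, `r2` (goodness of the log-log fit), and
#'   `n_used` (usable lags).
#' @export
estimate_alpha <- function(msd, fit_window = 1:10) {
  fit_window <- fit_window[fit_window <= nrow(msd)]
  v <- msd$msd_um2[fit_window]
  ok <- !is.na(v) & v > 0
  if (sum(ok) < 3)
    return(list(alpha = NA_real_, r2 = NA_real_, n_used = sum(ok)))
  lx <- log(msd$lag_s[fit_window][ok]); ly <- log(v[ok])
  fit <- ols_fit(lx, ly)
  list(alpha = unname(fit[["slope"]]), r2 = unname(ols_r2(lx, ly, fit)),
       n_used = sum(ok))
}

#' Alpha thresholds for motion-mode classification
#'
#' @param confined_max alpha below which motion is called confined
#'   (default 0.7).
#' @param directed_min alpha above which motion is called directed
#'   (default 1.3).
#' @return an `alpha_thresholds` object.
#' @export
alpha_thresholds <- function(confined_max = 0.7, directed_min = 1.3) {
  check_num(confined_max, "confined_max", positive = TRUE)
  check_num(directed_min, "directed_min", positive = TRUE)
  if (!(confined_max < directed_min) || directed_min >= 2.5)
    stop_bad("thresholds", "need 0 < confined_max < directed_min < 2.5")
  structure(list(confined_max = confined_max, directed_min = directed_min),
            class = "alpha_thresholds")
}

#' Classify motion mode from the anomalous exponent
#'
#' `alpha < confined_max` is confined; `alpha > directed_min` is directed;
#' anything else -- including exact threshold equality (tie-break toward the
#' middle class) -- is Brownian.
#'
#' @param alpha numeric vector of exponents (NA allowed; propagated).
#' @param thresholds an [alpha_thresholds()] object.
#' @return character vector of modes.
#' @export
classify_mode <- function(alpha, thresholds = alpha_thresholds()) {
  stopifnot(inherits(thresholds, "alpha_thresholds"))
  out <- ifelse(alpha < thresholds$confined_max, "confined",
                ifelse(alpha > thresholds$directed_min, "directed", "brownian"))
  out[is.na(alpha)] <- NA_character_
  out
}

#' Per-trajectory motion analysis
#'
#' Runs the MSD pipeline over a trajectory table: time-averaged MSD, D from
#' the first `n_fit` lags, alpha over `alpha_lags` (capped at a quarter of
#' the trajectory length), and mode classification.
#'
#' @param trajs trajectory table (`traj_id`, `frame`, `x_um`, `y_um`, and
#'   optionally `true_mode`, `true_D`).
#' @param dt frame interval (s).
#' @param n_fit lags in the D fit (default 4).
#' @param alpha_lags lag window for the alpha fit (default `1:10`).
#' @param thresholds an [alpha_thresholds()].
#' @param min_len trajectories shorter than this are dropped (counted in the
#'   `dropped_short` attribute; default 20 frames).
#' @return fits table: `traj_id`, `D_um2_s`, `intercept_um2`, `alpha`,
#'   `mode`, `r2`, `n_frames`, `flagged`, plus `true_mode` / `true_D` when
#'   present. Attributes `dropped_short` and `alpha_undefined` count
#'   excluded records.
#' @export
fit_motion <- function(trajs, dt, n_fit = 4L, alpha_lags = 1:10,
                       thresholds = alpha_thresholds(), min_len = 20L) {
  parts <- split(trajs, trajs$traj_id)
  keep <- vapply(parts, nrow, 0L) >= min_len
  dropped <- sum(!keep)
  parts <- parts[keep]
  rows <- lapply(parts, function(tr) {
    n <- nrow(tr)
    cap <- max(3L, floor(n / 4))
    ml <- min(max(max(alpha_lags), n_fit), cap)
    msd <- compute_tamsd(tr, dt, max_lag = max(ml, n_fit), min_len = min_len)
    dfit <- estimate_D(msd, n_fit)
    afit <- estimate_alpha(msd, alpha_lags[alpha_lags <= cap])
    data.frame(traj_id = tr$traj_id[1], D_um2_s = dfit$D,
               intercept_um2 = dfit$intercept, alpha = afit$alpha,
               r2 = afit$r2, n_frames = n, flagged = dfit$flagged,
               true_mode = if ("true_mode" %in% names(tr)) tr$true_mode[1] else NA,
               true_D = if ("true_D" %in% names(tr)) tr$true_D[1] else NA,
               stringsAsFactors = FALSE)
  })
  fits <- do.call(rbind, rows)
  rownames(fits) <- NULL
  fits$mode <- classify_mode(fits$alpha, thresholds)
  fits <- fits[, c("traj_id", "D_um2_s", "intercept_um2", "alpha", "mode",
                   "r2", "n_frames", "flagged", "true_mode", "true_D")]
  attr(fits, "dropped_short") <- dropped
  attr(fits, "alpha_undefined") <- sum(is.na(fits$alpha))
  fits
}

#' Robustness of mode fractions to the alpha thresholds
#'
#' Classifies the supplied exponents at every point of a threshold grid and
#' reports the three mode fractions per grid point, together with the
#' maximum absolute change of each fraction across the grid.
#'
#' @param alphas numeric vector of per-trajectory exponents (>= 100 values;
#'   NAs dropped).
#' @param confined_grid,directed_grid grids for the two thresholds (defaults
#'   0.5--0.9 and 1.1--1.5 in steps of 0.1); the full Cartesian product is
#'   evaluated. Invalid combinations are skipped with a warning.
#' @return list with `table` (data.frame: `confined_max`, `directed_min`,
#'   `frac_confined`, `frac_brownian`, `frac_directed`) and `max_change`
#'   (named numeric, per mode).
#' @export
threshold_sweep <- function(alphas, confined_grid = seq(0.5, 0.9, by = 0.1),
                            directed_grid = seq(1.1, 1.5, by = 0.1)) {
  alphas <- alphas[!is.na(alphas)]
  if (length(alphas) < 100)
    stop_bad("alphas", "need at least 100 defined exponents")
  rows <- list()
  for (cm in confined_grid) for (dm in directed_grid) {
    th <- tryCatch(alpha_thresholds(cm, dm), error = function(e) NULL)
    if (is.null(th)) {
      warning(sprintf("skipping invalid grid point (%.2f, %.2f)", cm, dm))
      next
    }
    cl <- classify_mode(alphas, th)
    rows[[length(rows) + 1L]] <- data.frame(
      confined_max = cm, directed_min = dm,
      frac_confined = mean(cl == "confined"),
      frac_brownian = mean(cl == "brownian"),
      frac_directed = mean(cl == "directed"))
  }
  tab <- do.call(rbind, rows)
  mc <- vapply(c("frac_confined", "frac_brownian", "frac_directed"),
               function(cn) max(tab[[cn]]) - min(tab[[cn]]), 0)
  names(mc) <- sub("frac_", "", names(mc))
  list(table = tab, max_change = mc)
}
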
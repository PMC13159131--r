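# Synthetic trajectory generator: confined / Brownian / directed motion at
# 10 Hz with Gaussian localization noise, emulating low-density aptamer-dye
# labeling of a membrane receptor imaged by TIRF.

# Dimensionless shape constants tying the corral radius and drift speed to a
# trajectory's diffusion coefficient (tau0 = 1 s reference time):
#   confined:  R = sqrt(CORRAL_SCALE * D * tau0)
#   directed:  v = sqrt(DRIFT_SCALE  * D / tau0)
# Chosen so that over a ten-lag fit window at 10 Hz the three modes produce
# well-separated anomalous-exponent distributions (alpha ~ 0.38 / 1.0 / 1.6),
# making the mode classification robust across a wide threshold range.
CORRAL_SCALE <- 0.7
DRIFT_SCALE <- 20
TAU0 <- 1

MOTION_MODES <- c("confined", "brownian", "directed")

#' Motion-mode parameters
#'
#' Bundles the parameters of one diffusion mode: the diffusion coefficient
#' `D`, and, where applicable, the corral radius `R` (confined motion,
#' modeled as a reflecting circular corral about the start point) or the
#' drift speed `v` and heading (directed motion).
#'
#' When `R` or `v` is omitted they default to the package's calibrated
#' scaling with `D`: `R = sqrt(0.7 * D * 1s)` and `v = sqrt(20 * D / 1s)`.
#' These defaults keep the shape of the mean-squared-displacement curve --
#' and hence the anomalous exponent alpha -- independent of `D`, so that
#' populations spanning a broad range of mobilities classify consistently.
#'
#' @param mode one of `"confined"`, `"brownian"`, `"directed"`.
#' @param D diffusion coefficient (um^2/s), `>= 0`.
#' @param R corral radius (um); confined mode only, `> 0`.
#' @param v drift speed (um/s); directed mode only, `> 0`.
#' @param drift_heading drift direction (radians); directed mode only. If
#'   `NULL`, a heading is drawn uniformly per trajectory.
#' @param sdlog log-scale dispersion of per-trajectory D around `D` when the
#'   parameters are used in a population (lognormal; 0 disables spread).
#' @return an object of class `mode_params`.
#' @export
mode_params <- function(mode, D, R = NULL, v = NULL, drift_heading = NULL,
                        sdlog = 0.5) {
  mode <- match.arg(mode, MOTION_MODES)
  check_num(D, "D", nonneg = TRUE)
  check_num(sdlog, "sdlog", nonneg = TRUE)
  if (mode == "confined") {
    if (is.null(R)) R <- sqrt(CORRAL_SCALE * D * TAU0)
    check_num(R, "R", positive = TRUE)
  } else R <- NULL
  if (mode == "directed") {
    if (is.null(v)) v <- sqrt(DRIFT_SCALE * D / TAU0)
    check_num(v, "v", positive = TRUE)
    if (!is.null(drift_heading)) check_num(drift_heading, "drift_heading")
  } else {
    v <- NULL; drift_heading <- NULL
  }
  structure(list(mode = mode, D = D, R = R, v = v,
                 drift_heading = drift_heading, sdlog = sdlog),
            class = "mode_params")
}

#' Population specification for the trajectory generator
#'
#' Describes a heterogeneous population: per-mode probabilities, per-mode
#' motion parameters with a lognormal dispersion of D across trajectories,
#' and the imaging regime (frame interval, localization noise).
#'
#' @param fractions named numeric vector of mode probabilities over
#'   `confined`, `brownian`, `directed`; must sum to 1 (tolerance 1e-9).
#' @param mode_params named list of [mode_params()] objects, one per mode
#'   with nonzero fraction.
#' @param n_traj number of trajectories.
#' @param n_frames frames per trajectory (>= 2).
#' @param dt frame interval in seconds (default 0.1 s, i.e. 10 Hz imaging).
#' @param sigma_loc localization noise s.d. per axis (um; default 0.03).
#' @param seed integer root seed; every trajectory derives a child stream
#'   from it, so subsets are reproducible.
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(fractions, mode_params, n_traj, n_frames,
                            dt = 0.1, sigma_loc = 0.03, seed = 1L) {
  if (is.null(names(fractions)) || !all(names(fractions) %in% MOTION_MODES))
    stop_bad("fractions", "must be named with modes confined/brownian/directed")
  fractions <- fractions[fractions > 0]
  if (abs(sum(fractions) - 1) > 1e-9)
    stop_bad("fractions", "must sum to 1 (within 1e-9)")
  for (m in names(fractions)) {
    p <- mode_params[[m]]
    if (is.null(p) || !inherits(p, "mode_params") || p$mode != m)
      stop_bad("mode_params", sprintf("missing or mismatched entry for mode '%s'", m))
  }
  n_traj <- check_count(n_traj, "n_traj")
  n_frames <- check_count(n_frames, "n_frames", min = 2L)
  check_num(dt, "dt", positive = TRUE)
  check_num(sigma_loc, "sigma_loc", nonneg = TRUE)
  seed <- check_count(seed, "seed", min = 0L)
  structure(list(fractions = fractions, mode_params = mode_params[names(fractions)],
                 n_traj = n_traj, n_frames = n_frames, dt = dt,
                 sigma_loc = sigma_loc, seed = seed),
            class = "population_spec")
}

#' Simulate one trajectory
#'
#' Generates a single 2-D trajectory of the given motion mode, sampled at
#' `dt`, with independent Gaussian localization noise (s.d. `sigma_loc` per
#' axis) added to every reported position.
#'
#' Brownian motion uses independent per-axis Gaussian steps of variance
#' `2 * D * dt`. Directed motion adds a constant drift `v * dt` along the
#' heading. Confined motion reflects each step at a circular corral of
#' radius `R` centred on the start point (radial fold-back).
#'
#' @param params a [mode_params()] object (its `D` is used as-is; no
#'   population dispersion is applied here).
#' @param n_frames number of frames (>= 2).
#' @param dt frame interval (s), > 0.
#' @param sigma_loc localization noise s.d. per axis (um).
#' @param seed integer seed (required; determinism contract).
#' @param traj_id identifier stored in the output.
#' @return a data.frame with columns `traj_id`, `frame` (0-based), `x_um`,
#'   `y_um`, `true_mode`, `true_D`.
#' @export
simulate_trajectory <- function(params, n_frames, dt, sigma_loc = 0, seed,
                                traj_id = 1L) {
  stopifnot(inherits(params, "mode_params"))
  n_frames <- check_count(n_frames, "n_frames", min = 2L)
  check_num(dt, "dt", positive = TRUE)
  check_num(sigma_loc, "sigma_loc", nonneg = TRUE)
  seed <- check_count(seed, "seed", min = 0L)
  pos <- with_seed(seed, {
    sx <- rnorm(n_frames - 1, 0, sqrt(2 * params$D * dt))
    sy <- rnorm(n_frames - 1, 0, sqrt(2 * params$D * dt))
    p <- switch(params$mode,
      brownian = cbind(cumsum(c(0, sx)), cumsum(c(0, sy))),
      directed = {
        th <- params$drift_heading %||% runif(1, 0, 2 * pi)
        drift <- params$v * dt * (seq_len(n_frames) - 1)
        cbind(cumsum(c(0, sx)) + drift * cos(th),
              cumsum(c(0, sy)) + drift * sin(th))
      },
      confined = .reflect_walk(sx, sy, params$R))
    if (sigma_loc > 0)
      p <- p + matrix(rnorm(2 * n_frames, 0, sigma_loc), n_frames, 2)
    p
  })
  data.frame(traj_id = rep(traj_id, n_frames),
             frame = 0:(n_frames - 1),
             x_um = pos[, 1], y_um = pos[, 2],
             true_mode = params$mode, true_D = params$D,
             stringsAsFactors = FALSE)
}

#' Simulate a trajectory population
#'
#' Draws each trajectory's mode from `spec$fractions` and its diffusion
#' coefficient from a lognormal centred (in median) on the mode's `D` with
#' log-s.d. `sdlog`, then simulates it with [simulate_trajectory()]. The
#' corral radius and drift speed scale with the drawn D (see
#' [mode_params()]), keeping the MSD shape of each mode self-similar.
#'
#' Deterministic given `spec` (including `spec$seed`): trajectory `i` uses
#' the child stream `child_seed(seed, i)`.
#'
#' @param spec a [population_spec()].
#' @return trajectory table: data.frame with columns `traj_id`, `frame`,
#'   `x_um`, `y_um`, `true_mode`, `true_D`.
#' @export
simulate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  modes <- names(spec$fractions)
  draws <- with_seed(child_seed(spec$seed, 0L), {
    mode_i <- sample(modes, spec$n_traj, replace = TRUE, prob = spec$fractions)
    z <- rnorm(spec$n_traj)
    list(mode = mode_i, z = z)
  })
  out <- vector("list", spec$n_traj)
  for (i in seq_len(spec$n_traj)) {
    m <- draws$mode[i]
    base <- spec$mode_params[[m]]
    D_i <- base$D * exp(base$sdlog * draws$z[i])
    sc <- if (base$D > 0) sqrt(D_i / base$D) else 1
    p_i <- switch(m,
      confined = mode_params("confined", D_i, R = base$R * sc, sdlog = 0),
      brownian = mode_params("brownian", D_i, sdlog = 0),
      directed = mode_params("directed", D_i, v = base$v * sc,
                             drift_heading = base$drift_heading, sdlog = 0))
    out[[i]] <- simulate_trajectory(p_i, spec$n_frames, spec$dt,
                                    spec$sigma_loc,
                                    seed = child_seed(spec$seed, i),
                                    traj_id = i)
  }
  do.call(rbind, out)
}

#' Scale all diffusion coefficients of a population spec
#'
#' Multiplies every mode's D by `factor`, rescaling the tied corral radii
#' and drift speeds accordingly (R, v scale with sqrt(D)). Used to model
#' perturbations that uniformly slow down (factor < 1) or speed up receptor
#' diffusion, e.g. antibody crosslinking or EMT induction.
#'
#' @param spec a [population_spec()].
#' @param factor positive scale factor applied to D.
#' @return the modified `population_spec`.
#' @export
scale_spec <- function(spec, factor) {
  stopifnot(inherits(spec, "population_spec"))
  check_num(factor, "factor", positive = TRUE)
  spec$mode_params <- lapply(spec$mode_params, function(p) {
    p$D <- p$D * factor
    if (!is.null(p$R)) p$R <- p$R * sqrt(factor)
    if (!is.null(p$v)) p$v <- p$v * sqrt(factor)
    p
  })
  spec
}
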
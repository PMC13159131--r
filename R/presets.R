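# Cell-line presets calibrated so that the default analysis pipeline
# reproduces published pooled median diffusion coefficients and motion-mode
# fractions for pancreatic cell lines and one patient-derived primary line.

# published per-line statistics: mode fractions (confined/brownian/directed)
# and pooled median D (um^2/s). PAAD-21010 fractions are not published; the
# preset reuses the pipeline default fractions, flagged as unprinted.
.PRESET_TABLE <- list(
  "hTERT-HPNE" = list(fractions = c(confined = 0.68, brownian = 0.20, directed = 0.12),
                      median_D = 0.07, fractions_printed = TRUE),
  "MIA PaCa-2" = list(fractions = c(confined = 0.58, brownian = 0.24, directed = 0.18),
                      median_D = 0.10, fractions_printed = TRUE),
  "PANC-1"     = list(fractions = c(confined = 0.50, brownian = 0.29, directed = 0.21),
                      median_D = 0.13, fractions_printed = TRUE),
  "PaTu-8988t" = list(fractions = c(confined = 0.44, brownian = 0.32, directed = 0.24),
                      median_D = 0.18, fractions_printed = TRUE),
  "PAAD-21010" = list(fractions = c(confined = 0.50, brownian = 0.30, directed = 0.20),
                      median_D = 0.11, fractions_printed = FALSE)
)

# preset defaults: 400 frames (40 s at 10 Hz), 2000 trajectories
.PRESET_N_FRAMES <- 400L
.PRESET_N_TRAJ <- 2000L
.PRESET_DT <- 0.1
.PRESET_SIGMA_LOC <- 0.03
.PRESET_SDLOG <- 0.5
# relative apparent (pipeline-estimated) per-mode median D: the slower
# apparent mobility of confined receptors and the faster apparent mobility
# of directed ones, at a moderate 3x total spread
.APPARENT_RATIOS <- c(confined = 0.5, brownian = 1, directed = 1.5)
.CALIBRATION_SEED <- 764921L   # internal; independent of user seeds
.CAL_N_PER_MODE <- 700L        # trajectories per mode for bias measurement
.CAL_N_POOL <- 1500L           # trajectories for pooled-median bisection
.CAL_TOL <- 0.02               # relative tolerance on the pooled median

.preset_cache <- new.env(parent = emptyenv())

# Apparent-D sample for one mode at unit scale: simulate `n` trajectories at
# true median D = 1 with the mode's tied corral/drift scaling, run the
# default D estimator, return estimated and true D.
.apparent_sample <- function(mode, n, seed, n_frames = .PRESET_N_FRAMES) {
  p <- mode_params(mode, 1, sdlog = .PRESET_SDLOG)
  spec <- population_spec(setNames(1, mode), setNames(list(p), mode),
                          n_traj = n, n_frames = n_frames,
                          dt = .PRESET_DT, sigma_loc = .PRESET_SIGMA_LOC,
                          seed = seed)
  trajs <- simulate_population(spec)
  fits <- fit_motion(trajs, .PRESET_DT)
  list(D_hat = fits$D_um2_s, D_true = fits$true_D)
}

# Median ratio apparent/true per mode (the estimator's mode-dependent bias),
# measured once per session under the fixed calibration seed.
.mode_bias <- function() {
  if (!is.null(.preset_cache$bias)) return(.preset_cache$bias)
  b <- vapply(seq_along(MOTION_MODES), function(j) {
    s <- .apparent_sample(MOTION_MODES[j], .CAL_N_PER_MODE,
                          child_seed(.CALIBRATION_SEED, j))
    median(s$D_hat) / median(s$D_true)
  }, 0)
  names(b) <- MOTION_MODES
  .preset_cache$bias <- b
  b
}

# Pooled apparent-D sample at overall true scale `s` for given fractions.
# `ratios_true` are the per-mode true medians at s = 1.
.pooled_apparent <- function(s, fractions, ratios_true, seed) {
  modes <- names(fractions)
  nm <- with_seed(seed, as.vector(rmultinom(1, .CAL_N_POOL, fractions)))
  unlist(lapply(seq_along(modes), function(j) {
    if (nm[j] == 0) return(numeric(0))
    smp <- .apparent_sample(modes[j], nm[j], child_seed(seed, 10L + j))
    smp$D_hat * ratios_true[modes[j]] * s
  }))
}

.calibrate_preset <- function(name) {
  key <- paste0("cal_", name)
  if (!is.null(.preset_cache[[key]])) return(.preset_cache[[key]])
  info <- .PRESET_TABLE[[name]]
  bias <- .mode_bias()
  ratios_true <- .APPARENT_RATIOS / bias
  # apparent pooled median is (numerically exactly) linear in the overall
  # scale, because corral radius and drift speed are tied to D; bisection on
  # log-scale converges in a handful of steps under common random numbers
  pool_seed <- child_seed(.CALIBRATION_SEED, 100L + match(name, names(.PRESET_TABLE)))
  pooled1 <- .pooled_apparent(1, info$fractions, ratios_true, pool_seed)
  target <- info$median_D
  lo <- log(target / median(pooled1)) - log(4)
  hi <- lo + 2 * log(4)
  f <- function(ls) median(.pooled_apparent(exp(ls), info$fractions,
                                            ratios_true, pool_seed)) - target
  ls <- log(target / median(pooled1))
  for (iter in 1:20) {
    m <- f(ls)
    if (abs(m) / target <= .CAL_TOL) break
    if (m > 0) hi <- ls else lo <- ls
    ls <- (lo + hi) / 2
  }
  out <- list(scale = exp(ls), ratios_true = ratios_true, bias = bias)
  .preset_cache[[key]] <- out
  out
}

#' Calibrated cell-line population presets
#'
#' Returns a [population_spec()] whose mode fractions are the published
#' per-line triples and whose per-mode diffusion coefficients are calibrated
#' -- by seeded bisection through the default analysis pipeline -- so that
#' the pipeline's pooled median estimated D matches the published per-line
#' median (within 2%), with per-mode apparent medians in ratio 0.5 : 1 : 1.5
#' (confined : Brownian : directed).
#'
#' Because the short-lag MSD estimator reads confined motion low and
#' directed motion high, the calibrated *true* D values differ from the
#' apparent targets; the trajectory tables carry the true values in
#' `true_D`. Calibration is deterministic (fixed internal seed) and cached
#' for the session.
#'
#' Available presets: `hTERT-HPNE` (normal pancreatic epithelium),
#' `MIA PaCa-2`, `PANC-1` (primary pancreatic tumor), `PaTu-8988t`
#' (liver-metastasis-derived), `PAAD-21010` (patient-derived primary cells;
#' mode fractions unpublished, pipeline defaults used and flagged).
#'
#' @param name preset name (see above).
#' @param n_traj,n_frames population size (defaults 2000 x 400 frames).
#' @param seed root seed for the returned spec.
#' @param d_scale multiplier applied to all diffusion coefficients after
#'   calibration (perturbation experiments; see [scale_spec()]).
#' @return a `population_spec` with attributes `median_D_target` and
#'   `fractions_printed`.
#' @export
cell_line_preset <- function(name, n_traj = .PRESET_N_TRAJ,
                             n_frames = .PRESET_N_FRAMES, seed = 1L,
                             d_scale = 1) {
  if (!name %in% names(.PRESET_TABLE))
    stop(sprintf("unknown cell line '%s'; valid names: %s", name,
                 paste(names(.PRESET_TABLE), collapse = ", ")), call. = FALSE)
  info <- .PRESET_TABLE[[name]]
  cal <- .calibrate_preset(name)
  mp <- lapply(MOTION_MODES, function(m)
    mode_params(m, cal$ratios_true[[m]] * cal$scale, sdlog = .PRESET_SDLOG))
  names(mp) <- MOTION_MODES
  spec <- population_spec(info$fractions, mp, n_traj = n_traj,
                          n_frames = n_frames, dt = .PRESET_DT,
                          sigma_loc = .PRESET_SIGMA_LOC, seed = seed)
  if (d_scale != 1) spec <- scale_spec(spec, d_scale)
  attr(spec, "median_D_target") <- info$median_D * d_scale
  attr(spec, "fractions_printed") <- info$fractions_printed
  attr(spec, "cell_line") <- name
  spec
}
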
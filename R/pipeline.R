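# End-to-end pipeline: configuration document, movie/trajectory dispatch,
# filter ledger, reproducibility report.

.CONFIG_DEFAULTS <- list(
  dt = 0.1,                 # frame interval (s); 10 Hz imaging
  sigma_loc = 0.03,         # localization noise s.d. (um)
  pixel_size = 0.107,       # um per pixel
  psf_sigma = 0.15,         # PSF s.d. (um)
  threshold_factor = 5,     # detection threshold (robust s.d. units)
  r_max = 2.5,              # linking radius (um)
  gap_max = 1,              # closed gap (frames)
  min_len = 20,             # minimum trajectory length (frames)
  n_fit = 4,                # lags in the D fit
  alpha_lags_max = 10,      # last lag of the alpha fit window
  confined_max = 0.7,       # alpha threshold: confined below
  directed_min = 1.3,       # alpha threshold: directed above
  min_traj = 1000,          # trajectories required for a summary
  bleach_qc = FALSE,        # exclude movie-derived tracks with >= 2 bleach steps
  seed = 1
)

.CONFIG_BOUNDS <- list(
  dt = c(1e-6, Inf), sigma_loc = c(0, Inf), pixel_size = c(1e-6, Inf),
  psf_sigma = c(1e-6, Inf), threshold_factor = c(0, Inf), r_max = c(1e-6, Inf),
  gap_max = c(0, 100), min_len = c(2, Inf), n_fit = c(2, Inf),
  alpha_lags_max = c(3, Inf), confined_max = c(1e-6, 2.5),
  directed_min = c(1e-6, 2.5), min_traj = c(1, Inf), seed = c(0, 2^31 - 1)
)

#' Pipeline configuration
#'
#' A single flat key-value document holding every stage's tunable
#' parameters. Unknown keys are rejected; every value is checked against
#' its stated bounds.
#'
#' @param ... named overrides of the defaults (see
#'   `smtrack:::.CONFIG_DEFAULTS` for keys and defaults).
#' @param file optional YAML file of flat key-value overrides.
#' @return a validated `pipeline_config` (named list).
#' @export
pipeline_config <- function(..., file = NULL) {
  over <- list(...)
  if (!is.null(file)) {
    y <- yaml::read_yaml(file)
    if (!is.list(y)) stop(sprintf("%s: not a key-value mapping", file), call. = FALSE)
    over <- modifyList(y, over)
  }
  unknown <- setdiff(names(over), names(.CONFIG_DEFAULTS))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  cfg <- modifyList(.CONFIG_DEFAULTS, over)
  for (k in names(.CONFIG_BOUNDS)) {
    b <- .CONFIG_BOUNDS[[k]]
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < b[1] || v > b[2])
      stop_bad(k, sprintf("must be a number in [%g, %g]", b[1], b[2]))
  }
  if (!is.logical(cfg$bleach_qc) || length(cfg$bleach_qc) != 1)
    stop_bad("bleach_qc", "must be TRUE or FALSE")
  if (cfg$confined_max >= cfg$directed_min)
    stop_bad("confined_max", "must be < directed_min")
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Movie input (multi-page TIFF) runs detection, linking, optional
#' single-fluorophore bleach QC, MSD motion analysis, and a population
#' summary. Trajectory input (CSV) skips detection and linking. The report
#' accounts for every record entering each filter.
#'
#' @param input path to a `.tif`/`.tiff` movie or a trajectory `.csv`.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for `fits.csv`, `summary.csv` and
#'   `report.json`.
#' @param group_id label for the population summary.
#' @return list with `fits`, `summary` (a `population_summary`), `report`.
#' @export
run_pipeline <- function(input, config = pipeline_config(), out_dir = NULL,
                         group_id = "sample") {
  stopifnot(inherits(config, "pipeline_config"))
  if (!file.exists(input))
    stop(sprintf("%s: no such file", input), call. = FALSE)
  ext <- tolower(tools::file_ext(input))
  counts <- list()
  if (ext %in% c("tif", "tiff")) {
    stack <- read_movie(input)
    dets <- detect_stack(stack, config$pixel_size, config$psf_sigma,
                         config$threshold_factor)
    counts$detections <- nrow(dets)
    trajs <- link_detections(dets, link_config(r_max = config$r_max,
                                               gap_max = config$gap_max,
                                               min_len = config$min_len))
    counts$detections_linked <- nrow(trajs)
    counts$detections_unlinked <- attr(trajs, "n_unlinked")
    counts$trajectories <- length(unique(trajs$traj_id))
    if (nrow(trajs) == 0)
      stop(sprintf("%s: no trajectories of length >= %d", input, config$min_len),
           call. = FALSE)
    if (isTRUE(config$bleach_qc)) {
      keep <- vapply(split(trajs, trajs$traj_id), function(tr) {
        pos <- c(median(tr$x_um), median(tr$y_um))
        trace <- extract_trace(stack, pos, config$pixel_size)
        count_bleach_steps(trace)$n_steps <= 1
      }, TRUE)
      counts$trajectories_multi_step <- sum(!keep)
      trajs <- trajs[trajs$traj_id %in% names(keep)[keep], , drop = FALSE]
    }
  } else if (ext == "csv") {
    trajs <- read_trajectories(input)
    counts$trajectories <- length(unique(trajs$traj_id))
  } else {
    stop(sprintf("%s: unsupported input type '.%s' (need .tif/.tiff or .csv)",
                 input, ext), call. = FALSE)
  }
  fits <- fit_motion(trajs, dt = config$dt, n_fit = config$n_fit,
                     alpha_lags = seq_len(config$alpha_lags_max),
                     thresholds = alpha_thresholds(config$confined_max,
                                                   config$directed_min),
                     min_len = config$min_len)
  counts$trajectories_short_dropped <- attr(fits, "dropped_short")
  counts$trajectories_fit <- nrow(fits)
  counts$alpha_undefined <- attr(fits, "alpha_undefined")
  counts$classified <- nrow(fits) - attr(fits, "alpha_undefined")
  summary <- summarize_population(fits, group_id = group_id,
                                  min_traj = config$min_traj,
                                  override = nrow(fits) < config$min_traj)
  report <- list(
    input = input,
    config = unclass(config),
    config_hash = fnv1a_hash(paste(names(config), unlist(config),
                                   collapse = ";")),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("smtrack")),
    counts = counts,
    summary = list(group_id = summary$group_id, n_traj = summary$n_traj,
                   median_D = summary$median_D, D_iqr = summary$D_iqr,
                   mode_fractions = as.list(summary$mode_fractions))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fits(fits, file.path(out_dir, "fits.csv"))
    sm <- data.frame(group_id = summary$group_id, n_traj = summary$n_traj,
                     median_D = summary$median_D, D_iqr = summary$D_iqr,
                     frac_confined = summary$mode_fractions[["confined"]],
                     frac_brownian = summary$mode_fractions[["brownian"]],
                     frac_directed = summary$mode_fractions[["directed"]])
    write.csv(sm, file.path(out_dir, "summary.csv"), row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(fits = fits, summary = summary, report = report)
}
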
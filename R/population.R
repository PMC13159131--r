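# Population-level statistics: per-group summaries, ANOVA + Tukey group
# comparisons, mobility-phenotype correlation, perturbation percent change.

#' Summarize per-trajectory fits for one group
#'
#' Median and IQR of the per-trajectory diffusion coefficients (all
#' trajectories, including those with undefined alpha) and motion-mode
#' fractions over the classified trajectories.
#'
#' @param fits fits table from [fit_motion()].
#' @param group_id label stored in the summary.
#' @param min_traj minimum trajectories required (default 1000, the
#'   reporting convention for per-line statistics); fewer are rejected
#'   unless `override = TRUE` (with a warning).
#' @param override allow summaries below `min_traj`.
#' @return a `population_summary`: list with `group_id`, `n_traj`,
#'   `median_D`, `D_iqr`, `mode_fractions`, `n_classified`,
#'   `n_alpha_undefined`.
#' @export
summarize_population <- function(fits, group_id = "group", min_traj = 1000L,
                                 override = FALSE) {
  n <- nrow(fits)
  if (n < 1) stop_bad("fits", "no trajectories")
  if (n < min_traj) {
    if (!override)
      stop(sprintf("group '%s' has %d trajectories (< min_traj = %d); use override = TRUE",
                   group_id, n, min_traj), call. = FALSE)
    warning(sprintf("group '%s': summarizing %d < %d trajectories (override)",
                    group_id, n, min_traj))
  }
  cl <- fits$mode[!is.na(fits$mode)]
  fr <- vapply(MOTION_MODES, function(m) mean(cl == m), 0)
  structure(list(group_id = group_id, n_traj = n,
                 median_D = median(fits$D_um2_s),
                 D_iqr = unname(diff(quantile(fits$D_um2_s, c(0.25, 0.75)))),
                 mode_fractions = fr,
                 n_classified = length(cl),
                 n_alpha_undefined = sum(is.na(fits$mode))),
            class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("Population '%s': %d trajectories (%d classified, %d alpha undefined)\n",
              x$group_id, x$n_traj, x$n_classified, x$n_alpha_undefined))
  cat(sprintf("  median D = %.4f um^2/s (IQR %.4f)\n", x$median_D, x$D_iqr))
  cat(sprintf("  mode fractions: confined %.1f%%, brownian %.1f%%, directed %.1f%%\n",
              100 * x$mode_fractions[["confined"]],
              100 * x$mode_fractions[["brownian"]],
              100 * x$mode_fractions[["directed"]]))
  invisible(x)
}

#' Compare diffusion coefficients across groups
#'
#' One-way ANOVA over the per-trajectory D values followed by Tukey's
#' honest-significant-difference test for all pairwise contrasts.
#'
#' @param groups named list of numeric vectors (per-trajectory D per group),
#'   each of length >= 3.
#' @return list with `F`, `p` (ANOVA), `pairwise` (data.frame: `pair`,
#'   `diff`, `p_adj`), and `method`.
#' @export
compare_groups <- function(groups) {
  if (length(groups) < 2) stop_bad("groups", "need at least 2 groups")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  ns <- lengths(groups)
  if (any(ns < 3)) stop_bad("groups", "each group needs n >= 3")
  df <- data.frame(D = unlist(groups, use.names = FALSE),
                   group = factor(rep(names(groups), ns)))
  fit <- aov(D ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  pairwise <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                         p_adj = tk[, "p adj"], row.names = NULL)
  list(F = an["group", "F value"], p = an["group", "Pr(>F)"],
       pairwise = pairwise,
       method = "one-way ANOVA with Tukey HSD multiple comparisons")
}

#' Correlate group mobility with a phenotype
#'
#' Pearson correlation between per-group median diffusion coefficients and
#' an externally measured phenotype (e.g. wound-closure rate, transwell
#' migration counts). The phenotype values are supplied numbers; this
#' package never derives them from images.
#'
#' @param median_D numeric vector of group median D values.
#' @param phenotype numeric vector of the same length (n >= 3).
#' @return list with `r`, `p` (two-sided), `n`, `method`.
#' @export
correlate_mobility <- function(median_D, phenotype) {
  if (length(median_D) != length(phenotype))
    stop_bad("phenotype", "must have the same length as median_D")
  if (length(median_D) < 3) stop_bad("median_D", "need n >= 3")
  if (sd(median_D) == 0 || sd(phenotype) == 0)
    stop("correlation undefined: zero variance in input", call. = FALSE)
  ct <- cor.test(median_D, phenotype, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(median_D),
       method = "Pearson correlation, two-sided")
}

#' Percent change in median D between conditions
#'
#' `100 * (median_treated - median_control) / median_control`, with a
#' seeded percentile bootstrap confidence interval over trajectory
#' resampling within each group.
#'
#' @param fits_control,fits_treated fits tables (or numeric vectors of
#'   per-trajectory D).
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @return list with `percent_change`, `ci` (length-2), `median_control`,
#'   `median_treated`, `n_boot`, `seed`.
#' @export
percent_change <- function(fits_control, fits_treated, n_boot = 2000L,
                           seed = 1L, conf = 0.95) {
  dc <- if (is.data.frame(fits_control)) fits_control$D_um2_s else fits_control
  dtr <- if (is.data.frame(fits_treated)) fits_treated$D_um2_s else fits_treated
  if (length(dc) == 0 || length(dtr) == 0)
    stop_bad("fits", "both groups must be nonempty")
  mc <- median(dc); mt <- median(dtr)
  if (mc == 0) stop("control median is 0; percent change undefined", call. = FALSE)
  n_boot <- check_count(n_boot, "n_boot")
  pc <- 100 * (mt - mc) / mc
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    bmc <- median(dc[sample.int(length(dc), replace = TRUE)])
    bmt <- median(dtr[sample.int(length(dtr), replace = TRUE)])
    100 * (bmt - bmc) / bmc
  }, 0))
  a <- (1 - conf) / 2
  list(percent_change = pc,
       ci = unname(quantile(boots, c(a, 1 - a))),
       median_control = mc, median_treated = mt,
       n_boot = n_boot, seed = seed)
}
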
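# Density-based cluster analysis of super-resolution localizations
# (dSTORM-style point patterns): DBSCAN clustering with radius-of-gyration
# and convex-hull size metrics.

#' Density-based clustering of localization points
#'
#' DBSCAN: a point with at least `min_pts` neighbours within `eps`
#' (including itself) is a core point; clusters are the connected
#' components of core points within `eps`, plus border points (non-core
#' points within `eps` of a core point). Remaining points are noise.
#'
#' Cluster size is reported as the radius of gyration (RMS distance of the
#' cluster's points from their centroid) with the convex-hull area
#' alongside.
#'
#' @param points data.frame with columns `x_um`, `y_um` (or a 2-column
#'   matrix), at least `min_pts` rows.
#' @param eps neighbourhood radius (um), > 0 (default 0.05).
#' @param min_pts core-point threshold (default 10).
#' @return a `cluster_result`: list with `n_clusters`, `clusters`
#'   (data.frame: `cluster`, `n_points`, `rg_um`, `hull_area_um2`),
#'   `labels` (0 = noise), `noise_fraction`.
#' @export
cluster_points <- function(points, eps = 0.05, min_pts = 10L) {
  if (is.matrix(points)) points <- data.frame(x_um = points[, 1], y_um = points[, 2])
  check_num(eps, "eps", positive = TRUE)
  min_pts <- check_count(min_pts, "min_pts")
  n <- nrow(points)
  if (n < min_pts)
    stop_bad("points", sprintf("need at least min_pts = %d points", min_pts))
  x <- points$x_um; y <- points$y_um
  if (anyNA(x) || anyNA(y)) stop_bad("points", "positions must be finite")

  # neighbour lists on a full distance matrix; localization datasets at this
  # scale (<= a few 10^4 points) fit comfortably
  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  nb <- apply(d2 <= eps^2, 1, which, simplify = FALSE)
  core <- lengths(nb) >= min_pts

  labels <- integer(n)  # 0 = unassigned/noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      j <- queue[[1]]; queue <- queue[-1]
      for (k in nb[[j]]) {
        if (labels[k] == 0L) {
          labels[k] <- cl
          if (core[k]) queue <- c(queue, k)
        }
      }
    }
  }
  ids <- seq_len(cl)
  stats <- lapply(ids, function(id) {
    px <- x[labels == id]; py <- y[labels == id]
    cx <- mean(px); cy <- mean(py)
    rg <- sqrt(mean((px - cx)^2 + (py - cy)^2))
    hull <- grDevices::chull(px, py)
    hx <- px[hull]; hy <- py[hull]
    area <- if (length(hull) >= 3)
      abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2 else 0
    data.frame(cluster = id, n_points = length(px), rg_um = rg,
               hull_area_um2 = area)
  })
  clusters <- if (cl > 0) do.call(rbind, stats) else
    data.frame(cluster = integer(0), n_points = integer(0),
               rg_um = numeric(0), hull_area_um2 = numeric(0))
  structure(list(n_clusters = cl, clusters = clusters, labels = labels,
                 noise_fraction = mean(labels == 0L)),
            class = "cluster_result")
}

#' Compare cluster-size distributions between two samples
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test on the per-cluster
#' radius-of-gyration distributions of two clustering results.
#'
#' @param result_a,result_b `cluster_result` objects with >= 3 clusters
#'   each.
#' @return list with `statistic`, `p`, `median_rg` (named, per sample),
#'   `larger` (which sample has the larger median radius), `method`.
#' @export
compare_cluster_sizes <- function(result_a, result_b) {
  stopifnot(inherits(result_a, "cluster_result"),
            inherits(result_b, "cluster_result"))
  ra <- result_a$clusters$rg_um; rb <- result_b$clusters$rg_um
  if (length(ra) < 3 || length(rb) < 3)
    stop("need at least 3 clusters per sample", call. = FALSE)
  wt <- suppressWarnings(wilcox.test(ra, rb, alternative = "two.sided"))
  med <- c(a = median(ra), b = median(rb))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       median_rg = med,
       larger = if (med[["a"]] >= med[["b"]]) "a" else "b",
       method = "two-sided Mann-Whitney rank-sum on radius of gyration")
}
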
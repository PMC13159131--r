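# Frame-to-frame trajectory linking: optimal bipartite assignment by total
# squared displacement (Hungarian algorithm) with gap closing and a greedy
# fallback for pathologically dense frame pairs.

#' Linking configuration
#'
#' @param r_max maximum per-frame displacement (um). The default
#'   `4 * sqrt(4 * D_max * dt)` with `D_max = 1` um^2/s and `dt = 0.1` s
#'   (about 2.5 um) keeps the miss probability below 1e-3 for the mobility
#'   range of membrane receptors.
#' @param gap_max maximum number of missing frames closed (default 1).
#' @param min_len minimum trajectory length kept (default 20 frames).
#' @param greedy_limit frame pairs with more candidates than this fall back
#'   to greedy nearest-neighbour matching with a warning (default 500).
#' @return a `link_config` object.
#' @export
link_config <- function(r_max = 4 * sqrt(4 * 1 * 0.1), gap_max = 1L,
                        min_len = 20L, greedy_limit = 500L) {
  check_num(r_max, "r_max", positive = TRUE)
  gap_max <- check_count(gap_max, "gap_max", min = 0L)
  min_len <- check_count(min_len, "min_len", min = 2L)
  structure(list(r_max = r_max, gap_max = gap_max, min_len = min_len,
                 greedy_limit = greedy_limit),
            class = "link_config")
}

# optimal matching between two point sets: returns integer vector over rows
# of a (0 = unmatched); squared distance cost, pairs beyond r_max forbidden,
# unmatched option at cost r_max^2 (standard augmented square formulation)
.match_frames <- function(ax, ay, bx, by, r_max, greedy_limit = 500L) {
  n1 <- length(ax); n2 <- length(bx)
  if (n1 == 0 || n2 == 0) return(integer(n1))
  d2 <- outer(ax, bx, "-")^2 + outer(ay, by, "-")^2
  r2 <- r_max^2
  if (n1 + n2 > greedy_limit) {
    warning("dense frame pair: falling back to greedy matching")
    return(.match_greedy(d2, r2))
  }
  big <- 4 * r2 + 1
  n <- n1 + n2
  cost <- matrix(0, n, n)
  d2c <- pmin(d2, big)
  d2c[d2 > r2] <- big
  cost[seq_len(n1), seq_len(n2)] <- d2c
  cost[seq_len(n1), n2 + seq_len(n1)] <- big
  cost[n1 + seq_len(n2), seq_len(n2)] <- big
  for (i in seq_len(n1)) cost[i, n2 + i] <- r2
  for (j in seq_len(n2)) cost[n1 + j, j] <- r2
  assign <- .solve_assignment(cost)
  m <- assign[seq_len(n1)]
  m[m > n2] <- 0L
  # forbidden assignments chosen only when a point has no valid partner
  m[m > 0 & d2[cbind(seq_len(n1), pmax(m, 1))] > r2] <- 0L
  m
}

.match_greedy <- function(d2, r2) {
  n1 <- nrow(d2); n2 <- ncol(d2)
  m <- integer(n1)
  ord <- order(d2)
  used_b <- logical(n2)
  for (idx in ord) {
    if (d2[idx] > r2) break
    i <- (idx - 1) %% n1 + 1; j <- (idx - 1) %/% n1 + 1
    if (m[i] == 0 && !used_b[j]) { m[i] <- j; used_b[j] <- TRUE }
  }
  m
}

#' Link detections into trajectories
#'
#' Consecutive frames are matched by the assignment minimizing total
#' squared displacement among pairs within `r_max` (Hungarian algorithm;
#' each detection may stay unmatched at cost `r_max^2`). Track ends may
#' then be joined to later track starts across at most `gap_max` missing
#' frames, by ascending displacement cost scaled by gap length, provided
#' the displacement stays within `r_max * sqrt(gap + 1)`. Trajectories
#' shorter than `min_len` are discarded; each detection belongs to at most
#' one trajectory.
#'
#' @param detections data.frame with `frame` (0-based), `x_um`, `y_um`,
#'   sorted by frame (any other columns are carried along).
#' @param config a [link_config()].
#' @return trajectory table (`traj_id`, `frame`, `x_um`, `y_um`,
#'   `true_mode` = NA, `true_D` = NA), with attribute `n_unlinked`
#'   (detections not in any kept trajectory).
#' @export
link_detections <- function(detections, config = link_config()) {
  stopifnot(inherits(config, "link_config"))
  empty <- data.frame(traj_id = integer(0), frame = integer(0),
                      x_um = numeric(0), y_um = numeric(0),
                      true_mode = character(0), true_D = numeric(0))
  if (nrow(detections) == 0) return(empty)
  if (is.unsorted(detections$frame)) stop_bad("detections", "must be sorted by frame")
  frames <- sort(unique(detections$frame))
  byf <- split(seq_len(nrow(detections)), detections$frame)
  track_of <- integer(nrow(detections))  # 0 = unassigned
  next_id <- 0L
  # active tracks: last detection row per track
  last_row <- integer(0)   # indexed by track id
  for (i in seq_len(nrow(detections))[detections$frame == frames[1]]) {
    next_id <- next_id + 1L; track_of[i] <- next_id; last_row[next_id] <- i
  }
  for (fi in seq_along(frames)[-1]) {
    prev_rows <- byf[[as.character(frames[fi - 1])]]
    cur_rows <- byf[[as.character(frames[fi])]]
    contiguous <- frames[fi] - frames[fi - 1] == 1
    m <- if (contiguous && length(prev_rows))
      .match_frames(detections$x_um[prev_rows], detections$y_um[prev_rows],
                    detections$x_um[cur_rows], detections$y_um[cur_rows],
                    config$r_max, config$greedy_limit)
    else integer(length(prev_rows))
    matched_cur <- integer(length(cur_rows))
    for (k in seq_along(prev_rows)) {
      if (m[k] > 0) {
        tid <- track_of[prev_rows[k]]
        row <- cur_rows[m[k]]
        track_of[row] <- tid
        last_row[tid] <- row
        matched_cur[m[k]] <- 1L
      }
    }
    for (j in which(matched_cur == 0L)) {
      next_id <- next_id + 1L
      track_of[cur_rows[j]] <- next_id
      last_row[next_id] <- cur_rows[j]
    }
  }
  # gap closing: join a track's last detection to a later track's first
  # detection across <= gap_max missing frames, ascending cost = d^2 / gap
  if (config$gap_max > 0 && next_id > 1) {
    first_row <- vapply(seq_len(next_id), function(t) min(which(track_of == t)), 0L)
    last_row2 <- vapply(seq_len(next_id), function(t) max(which(track_of == t)), 0L)
    ends <- data.frame(t = seq_len(next_id), row = last_row2,
                       frame = detections$frame[last_row2])
    starts <- data.frame(t = seq_len(next_id), row = first_row,
                         frame = detections$frame[first_row])
    cand <- list()
    for (e in seq_len(nrow(ends))) {
      gap <- starts$frame - ends$frame[e] - 1L
      ok <- which(gap >= 1 & gap <= config$gap_max & starts$t != ends$t[e])
      for (s in ok) {
        d2 <- (detections$x_um[ends$row[e]] - detections$x_um[starts$row[s]])^2 +
              (detections$y_um[ends$row[e]] - detections$y_um[starts$row[s]])^2
        g <- gap[s] + 1L
        if (d2 <= config$r_max^2 * g)
          cand[[length(cand) + 1L]] <- c(ends$t[e], starts$t[s], d2 / g)
      }
    }
    if (length(cand)) {
      cand <- do.call(rbind, cand)
      cand <- cand[order(cand[, 3]), , drop = FALSE]
      alias <- list()
      closed_end <- logical(next_id); closed_start <- logical(next_id)
      for (r in seq_len(nrow(cand))) {
        te <- cand[r, 1]; ts <- cand[r, 2]
        if (closed_end[te] || closed_start[ts]) next
        # relabel ts into (the current label of) te
        te2 <- te
        while (!is.null(alias[[as.character(te2)]])) te2 <- alias[[as.character(te2)]]
        if (te2 == ts) next
        track_of[track_of == ts] <- te2
        alias[[as.character(ts)]] <- te2
        closed_end[te] <- TRUE; closed_start[ts] <- TRUE
      }
    }
  }
  # keep tracks >= min_len, renumber consecutively
  lens <- table(track_of[track_of > 0])
  keep <- as.integer(names(lens)[lens >= config$min_len])
  sel <- track_of %in% keep
  ids_new <- setNames(seq_along(keep), keep)
  out <- data.frame(traj_id = as.integer(ids_new[as.character(track_of[sel])]),
                    frame = detections$frame[sel],
                    x_um = detections$x_um[sel],
                    y_um = detections$y_um[sel],
                    true_mode = NA_character_, true_D = NA_real_)
  out <- out[order(out$traj_id, out$frame), ]
  rownames(out) <- NULL
  attr(out, "n_unlinked") <- nrow(detections) - nrow(out)
  out
}
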
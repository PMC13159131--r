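# File formats: trajectory / detection / fits CSV dialects, multi-page
# 16-bit TIFF movies, flat YAML configuration.

.TRAJ_COLS <- c("traj_id", "frame", "x_um", "y_um", "true_mode", "true_D")
.DET_COLS <- c("frame", "x_um", "y_um", "intensity", "width_um", "quality")
.FITS_COLS <- c("traj_id", "D_um2_s", "alpha", "mode", "r2", "n_frames")

#' Read / write trajectory tables
#'
#' CSV dialect: comma-separated, UTF-8, header
#' `traj_id,frame,x_um,y_um,true_mode,true_D`; positions in um, frames
#' 0-based. Ground-truth columns may be empty.
#'
#' @param path file path.
#' @param trajs trajectory table.
#' @return `read_trajectories` returns the validated table.
#' @export
read_trajectories <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("traj_id", "frame", "x_um", "y_um"), names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (nrow(df) == 0) stop(sprintf("%s: empty trajectory file", path), call. = FALSE)
  bad <- !is.finite(df$x_um) | !is.finite(df$y_um)
  if (any(bad))
    stop(sprintf("%s: non-finite position at line %d", path, which(bad)[1] + 1L),
         call. = FALSE)
  if (!"true_mode" %in% names(df)) df$true_mode <- NA_character_
  if (!"true_D" %in% names(df)) df$true_D <- NA_real_
  df[, .TRAJ_COLS]
}

#' @rdname read_trajectories
#' @export
write_trajectories <- function(trajs, path) {
  write.csv(trajs[, .TRAJ_COLS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write detection tables
#'
#' CSV dialect: header `frame,x_um,y_um,intensity,width_um,quality`.
#'
#' @param path file path.
#' @param detections detections table.
#' @export
read_detections <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("frame", "x_um", "y_um"), names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  for (cn in setdiff(.DET_COLS, names(df))) df[[cn]] <- NA_real_
  df[order(df$frame), .DET_COLS]
}

#' @rdname read_detections
#' @export
write_detections <- function(detections, path) {
  write.csv(detections[, .DET_COLS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write per-trajectory fits
#'
#' CSV dialect: header `traj_id,D_um2_s,alpha,mode,r2,n_frames`.
#'
#' @param path file path.
#' @param fits fits table from [fit_motion()].
#' @export
read_fits <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.FITS_COLS, names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  df
}

#' @rdname read_fits
#' @export
write_fits <- function(fits, path) {
  write.csv(fits[, intersect(c(.FITS_COLS, "intercept_um2", "flagged",
                               "true_mode", "true_D"), names(fits))],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write MSD curves in long format
#'
#' CSV with header `traj_id,lag_s,msd_um2,n_pairs`.
#'
#' @param curves named list of `msd_curve` objects (names = trajectory ids).
#' @param path file path.
#' @export
write_msd_curves <- function(curves, path) {
  rows <- Map(function(cv, id) cbind(traj_id = id, cv), curves, names(curves))
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# photon counts are stored as 16-bit unsigned grey values
.TIFF_MAX <- 65535

#' Read / write movies as multi-page 16-bit TIFF
#'
#' Pixel values are photon counts clipped to `[0, 65535]`.
#'
#' @param path file path.
#' @param stack array `ny x nx x n_frames`.
#' @export
write_movie <- function(stack, path) {
  stopifnot(length(dim(stack)) == 3)
  pages <- lapply(seq_len(dim(stack)[3]), function(f)
    pmin(pmax(stack[, , f], 0), .TIFF_MAX) / .TIFF_MAX)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0)
    stop(sprintf("%s: no TIFF pages", path), call. = FALSE)
  arr <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (f in seq_along(pages)) {
    pg <- pages[[f]]
    if (!all(dim(pg) == dim(arr)[1:2]))
      stop(sprintf("%s: page %d has inconsistent dimensions", path, f),
           call. = FALSE)
    arr[, , f] <- round(pg * .TIFF_MAX)
  }
  arr
}

#' Write ground-truth tables from the renderer
#'
#' CSV with header `frame,traj_id,x_px,y_px,x_um,y_um,photons,alive`.
#'
#' @param truth truth table from [render_movie()].
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  cols <- c("frame", "traj_id", "x_px", "y_px", "x_um", "y_um", "photons", "alive")
  write.csv(truth[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
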
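# Spot detection and subpixel localization: difference-of-Gaussians
# band-pass, MAD-robust thresholding, local maxima, and least-squares fits
# of a pixel-integrated 2-D Gaussian. Plus labeling-density estimation and
# single-step photobleaching QC on intensity traces.

# 1-D Gaussian convolution matrix with replicated edges (kernel truncated
# at 3 sigma, rows renormalized); blur = K %*% img %*% t(K)
.gauss_conv_matrix <- function(n, sigma_px) {
  hw <- max(1L, ceiling(3 * sigma_px))
  kern <- exp(-(seq(-hw, hw))^2 / (2 * sigma_px^2))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- pmin(pmax((i - hw):(i + hw), 1L), n)  # replicate edges
    for (j in seq_along(idx)) K[i, idx[j]] <- K[i, idx[j]] + kern[j]
  }
  K / rowSums(K)
}

.dog_response <- function(img, sigma_px) {
  n1 <- nrow(img); n2 <- ncol(img)
  K1 <- .gauss_conv_matrix(n1, sigma_px)
  K1b <- .gauss_conv_matrix(n1, 2 * sigma_px)
  if (n2 == n1) { K2 <- K1; K2b <- K1b }
  else { K2 <- .gauss_conv_matrix(n2, sigma_px); K2b <- .gauss_conv_matrix(n2, 2 * sigma_px) }
  (K1 %*% img %*% t(K2)) - (K1b %*% img %*% t(K2b))
}

# least-squares fit of a pixel-integrated isotropic Gaussian + offset in a
# square window; returns NULL when the fit diverges
.fit_gaussian_spot <- function(win, x_lo, y_lo, pixel_size, sigma0) {
  ny <- nrow(win); nx <- ncol(win)
  xs <- (x_lo + seq_len(nx) - 1) * pixel_size   # left edges, um
  ys <- (y_lo + seq_len(ny) - 1) * pixel_size
  bg0 <- median(win)
  amp0 <- max(sum(win - bg0), 1)
  # centroid start
  w <- pmax(win - bg0, 0)
  tw <- sum(w)
  x0 <- if (tw > 0) sum(t(w) * (xs + pixel_size / 2)) / tw else mean(xs)
  y0 <- if (tw > 0) sum(w * (ys + pixel_size / 2)) / tw else mean(ys)
  resid_fun <- function(p) {
    ex <- .psf_axis(xs, pixel_size, p[1], exp(p[3]))
    ey <- .psf_axis(ys, pixel_size, p[2], exp(p[3]))
    as.vector(win - (exp(p[5]) * outer(ey, ex) + p[4]))
  }
  fit <- tryCatch(
    suppressWarnings(
      minpack.lm::nls.lm(par = c(x0, y0, log(sigma0), bg0, log(amp0)),
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 120))),
    error = function(e) NULL)
  if (is.null(fit) || fit$info %in% c(0, 9)) return(NULL)
  p <- fit$par
  list(x_um = p[1], y_um = p[2], width_um = exp(p[3]),
       intensity = exp(p[5]), background = p[4],
       rss = sum(fit$fvec^2))
}

#' Detect and localize spots in one frame
#'
#' Candidate maxima come from a difference-of-Gaussians band-pass response
#' thresholded at `threshold_factor` times the robust background s.d.
#' (median absolute deviation). Each candidate is refined by least-squares
#' fitting of a pixel-integrated isotropic 2-D Gaussian plus constant
#' offset in a window of half-width `3 * psf_sigma_guess`. Candidates whose
#' fit diverges, whose fitted width falls outside
#' `[0.5, 2] * psf_sigma_guess`, or whose refined position leaves the
#' window are dropped (not retried).
#'
#' @param frame_image numeric matrix (photons; rows = y).
#' @param pixel_size um per pixel.
#' @param psf_sigma_guess expected PSF s.d. (um).
#' @param threshold_factor detection threshold in robust s.d. units
#'   (default 5).
#' @return data.frame `x_um`, `y_um`, `intensity`, `width_um`, `quality`
#'   (peak response in robust s.d. units); empty for blank images.
#' @export
detect_spots <- function(frame_image, pixel_size, psf_sigma_guess = 0.12,
                         threshold_factor = 5) {
  stopifnot(is.matrix(frame_image))
  check_num(pixel_size, "pixel_size", positive = TRUE)
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      intensity = numeric(0), width_um = numeric(0),
                      quality = numeric(0))
  if (diff(range(frame_image)) == 0) return(empty)
  sig_px <- psf_sigma_guess / pixel_size
  resp <- .dog_response(frame_image, sig_px)
  s <- mad(resp)
  if (s <= 0) return(empty)
  thr <- median(resp) + threshold_factor * s
  ny <- nrow(resp); nx <- ncol(resp)
  # 3x3 local maxima above threshold, away from the border
  cand <- which(resp > thr, arr.ind = TRUE)
  cand <- cand[cand[, 1] > 1 & cand[, 1] < ny & cand[, 2] > 1 & cand[, 2] < nx, ,
               drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  is_max <- apply(cand, 1, function(rc) {
    patch <- resp[(rc[1] - 1):(rc[1] + 1), (rc[2] - 1):(rc[2] + 1)]
    resp[rc[1], rc[2]] >= max(patch)
  })
  cand <- cand[is_max, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  hw <- ceiling(3 * sig_px)
  out <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ry <- cand[i, 1]; rx <- cand[i, 2]
    y_lo <- max(0, ry - 1 - hw); y_hi <- min(ny - 1, ry - 1 + hw)
    x_lo <- max(0, rx - 1 - hw); x_hi <- min(nx - 1, rx - 1 + hw)
    win <- frame_image[(y_lo + 1):(y_hi + 1), (x_lo + 1):(x_hi + 1), drop = FALSE]
    fit <- .fit_gaussian_spot(win, x_lo, y_lo, pixel_size, psf_sigma_guess)
    if (is.null(fit)) next
    if (fit$width_um < 0.5 * psf_sigma_guess || fit$width_um > 2 * psf_sigma_guess)
      next
    if (fit$x_um < x_lo * pixel_size || fit$x_um > (x_hi + 1) * pixel_size ||
        fit$y_um < y_lo * pixel_size || fit$y_um > (y_hi + 1) * pixel_size)
      next
    if (fit$intensity <= 0) next
    out[[i]] <- data.frame(x_um = fit$x_um, y_um = fit$y_um,
                           intensity = fit$intensity, width_um = fit$width_um,
                           quality = (resp[ry, rx] - median(resp)) / s)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) empty else res
}

#' Detect spots in every frame of a stack
#'
#' @param stack array `ny x nx x n_frames` (photons).
#' @param pixel_size,psf_sigma_guess,threshold_factor see [detect_spots()].
#' @param frames optional subset of 0-based frame indices.
#' @return detections table with a 0-based `frame` column.
#' @export
detect_stack <- function(stack, pixel_size, psf_sigma_guess = 0.12,
                         threshold_factor = 5, frames = NULL) {
  stopifnot(length(dim(stack)) == 3)
  all_frames <- 0:(dim(stack)[3] - 1)
  if (is.null(frames)) frames <- all_frames
  frames <- intersect(frames, all_frames)
  out <- lapply(frames, function(f) {
    d <- detect_spots(stack[, , f + 1], pixel_size, psf_sigma_guess,
                      threshold_factor)
    if (nrow(d)) cbind(frame = f, d) else
      cbind(frame = integer(0), d)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Labeling density from detections
#'
#' Mean detections per frame divided by the field area. For density QC on
#' movies, restrict to the first frames (before appreciable bleaching) via
#' `frames`.
#'
#' @param detections detections table with a `frame` column.
#' @param field_area_um2 field area (um^2), > 0.
#' @param frames optional 0-based frame subset (e.g. `0:9`).
#' @return density in spots/um^2.
#' @export
estimate_density <- function(detections, field_area_um2, frames = NULL) {
  check_num(field_area_um2, "field_area_um2", positive = TRUE)
  if (!is.null(frames)) {
    n_frames <- length(frames)
    detections <- detections[detections$frame %in% frames, , drop = FALSE]
  } else {
    if (nrow(detections) == 0) return(0)
    n_frames <- length(unique(detections$frame))
  }
  if (n_frames == 0) stop_bad("detections", "need at least one frame")
  (nrow(detections) / n_frames) / field_area_um2
}

#' Intensity trace at a fixed position
#'
#' Per-frame background-subtracted intensity in a circular aperture:
#' summed pixels within `aperture_radius_px` of the position, minus the
#' local background (median of an annulus between the aperture and twice
#' its radius) scaled to the aperture area.
#'
#' @param stack array `ny x nx x n_frames` (photons).
#' @param position length-2 numeric `(x_um, y_um)`.
#' @param pixel_size um per pixel.
#' @param aperture_radius_px aperture radius in pixels (default 4).
#' @return an `intensity_trace`: data.frame `frame`, `value`, with
#'   attribute `clipped` set when the aperture hits the image edge.
#' @export
extract_trace <- function(stack, position, pixel_size, aperture_radius_px = 4) {
  stopifnot(length(dim(stack)) == 3, length(position) == 2)
  ny <- dim(stack)[1]; nx <- dim(stack)[2]; nf <- dim(stack)[3]
  cx <- position[1] / pixel_size; cy <- position[2] / pixel_size
  if (cx < 0 || cy < 0 || cx > nx || cy > ny)
    stop_bad("position", "outside the field")
  r <- aperture_radius_px
  gx <- (seq_len(nx) - 0.5); gy <- (seq_len(ny) - 0.5)
  d2 <- outer((gy - cy)^2, (gx - cx)^2, "+")
  ap <- d2 <= r^2
  ann <- d2 > r^2 & d2 <= (2 * r)^2
  clipped <- (cx - r < 0) || (cy - r < 0) || (cx + r > nx) || (cy + r > ny)
  vals <- vapply(seq_len(nf), function(f) {
    fr <- stack[, , f]
    bg <- if (any(ann)) median(fr[ann]) else 0
    sum(fr[ap]) - bg * sum(ap)
  }, 0)
  structure(data.frame(frame = 0:(nf - 1), value = vals),
            class = c("intensity_trace", "data.frame"),
            clipped = clipped)
}

# recursive binary segmentation of a trace mean with a BIC-style penalty;
# returns candidate change-point indices (position of the first frame of
# the new segment)
.binseg_steps <- function(v, lo, hi, penalty) {
  n <- hi - lo + 1
  if (n < 6) return(integer(0))
  seg <- v[lo:hi]
  rss0 <- sum((seg - mean(seg))^2)
  # best single split (each side >= 3 points)
  best <- NULL; best_rss <- Inf
  for (k in 3:(n - 3)) {
    a <- seg[1:k]; b <- seg[(k + 1):n]
    rss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (rss < best_rss) { best_rss <- rss; best <- k }
  }
  if (is.null(best)) return(integer(0))
  # information criterion: accept the split if it improves the fit enough
  if (n * log(best_rss / n) + penalty >= n * log(rss0 / n)) return(integer(0))
  cp <- lo + best  # first index of the right segment
  c(.binseg_steps(v, lo, cp - 1, penalty), cp,
    .binseg_steps(v, cp, hi, penalty))
}

#' Count photobleaching steps in an intensity trace
#'
#' Recursive binary change-point search on the trace mean with a
#' Bayesian-information penalty; only downward mean changes exceeding
#' 3 times the local noise s.d. count as bleach steps. A trace showing
#' exactly one bleach step is the signature of a single fluorophore;
#' two or more indicate overlapping emitters.
#'
#' @param trace an `intensity_trace` (or data.frame with `frame`, `value`),
#'   length >= 10.
#' @param penalty change-point acceptance penalty; default `3 * log(n)`.
#' @return list with `n_steps` and `step_frames` (frame of the first
#'   post-step sample for each accepted downward step).
#' @export
count_bleach_steps <- function(trace, penalty = NULL) {
  v <- trace$value
  n <- length(v)
  if (n < 10) stop_bad("trace", "need at least 10 frames")
  if (anyNA(v) || any(!is.finite(v))) stop_bad("trace", "values must be finite")
  if (is.null(penalty)) penalty <- 3 * log(n)
  cps <- sort(unique(.binseg_steps(v, 1L, n, penalty)))
  if (!length(cps))
    return(list(n_steps = 0L, step_frames = integer(0)))
  bounds <- c(1L, cps, n + 1L)
  seg_means <- vapply(seq_len(length(bounds) - 1),
                      function(i) mean(v[bounds[i]:(bounds[i + 1] - 1)]), 0)
  # local noise: robust s.d. of first differences within segments
  noise <- mad(diff(v)) / sqrt(2)
  if (noise <= 0) noise <- sd(v) / 10 + 1e-12
  keep <- which(diff(seg_means) < -3 * noise)
  list(n_steps = length(keep),
       step_frames = trace$frame[cps[keep]])
}
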
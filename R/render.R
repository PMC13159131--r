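# Camera model: render trajectories into synthetic TIRF movie frames with a
# Gaussian PSF, Poisson shot noise, constant background, and single-step
# photobleaching.

#' Movie rendering specification
#'
#' @param field_size field edge length (um); the field is square.
#' @param pixel_size um per pixel (default 0.107).
#' @param psf_sigma PSF Gaussian s.d. (um, default 0.12, diffraction-limited for a far-red dye at high NA).
#' @param photons_per_spot expected photons per emitter per frame
#'   (default 1000).
#' @param background expected background photons per pixel per frame
#'   (default 5).
#' @param bleach_prob per-frame single-step bleaching probability
#'   (default 0; an emitter that bleaches drops to background in one step
#'   and stays dark).
#' @return a `movie_spec` object. Warns when the PSF is undersampled
#'   (`pixel_size >= 2 * psf_sigma`).
#' @export
movie_spec <- function(field_size = 25.6, pixel_size = 0.107,
                       psf_sigma = 0.12, photons_per_spot = 1000,
                       background = 5, bleach_prob = 0) {
  check_num(field_size, "field_size", positive = TRUE)
  check_num(pixel_size, "pixel_size", positive = TRUE)
  check_num(psf_sigma, "psf_sigma", positive = TRUE)
  check_num(photons_per_spot, "photons_per_spot", positive = TRUE)
  check_num(background, "background", nonneg = TRUE)
  check_num(bleach_prob, "bleach_prob", nonneg = TRUE)
  if (bleach_prob >= 1) stop_bad("bleach_prob", "must be < 1")
  if (pixel_size >= 2 * psf_sigma)
    warning("pixel_size >= 2 * psf_sigma: the PSF is undersampled")
  structure(list(field_size = field_size, pixel_size = pixel_size,
                 psf_sigma = psf_sigma, photons_per_spot = photons_per_spot,
                 background = background, bleach_prob = bleach_prob,
                 n_px = as.integer(round(field_size / pixel_size))),
            class = "movie_spec")
}

#' Place trajectories at random offsets inside a field
#'
#' Trajectories from the generator start at the origin; this translates
#' each by a uniform random offset such that the whole track (plus
#' `margin`) stays inside `[0, field_size]^2`. Tracks too large for the
#' field are rejected with an error.
#'
#' @param trajs trajectory table.
#' @param field_size field edge (um).
#' @param seed integer seed.
#' @param margin border kept free (um, default 1).
#' @return the translated trajectory table.
#' @export
place_in_field <- function(trajs, field_size, seed, margin = 1) {
  parts <- split(trajs, trajs$traj_id)
  ids <- names(parts)
  offs <- with_seed(seed, {
    lapply(parts, function(tr) {
      rx <- range(tr$x_um); ry <- range(tr$y_um)
      lox <- margin - rx[1]; hix <- field_size - margin - rx[2]
      loy <- margin - ry[1]; hiy <- field_size - margin - ry[2]
      if (hix < lox || hiy < loy)
        stop(sprintf("trajectory %s does not fit inside the field", tr$traj_id[1]),
             call. = FALSE)
      c(runif(1, lox, hix), runif(1, loy, hiy))
    })
  })
  out <- Map(function(tr, o) { tr$x_um <- tr$x_um + o[1]; tr$y_um <- tr$y_um + o[2]; tr },
             parts, offs)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# pixel-integrated Gaussian PSF: expected photons in pixel i (0-based,
# covering [i, i+1) * pixel_size um) from an emitter at x0 um with total
# photon count N. Product of per-axis erf differences.
.psf_axis <- function(px_lo_um, pixel_size, x0, sigma) {
  pnorm(px_lo_um + pixel_size, x0, sigma) - pnorm(px_lo_um, x0, sigma)
}

#' Render trajectories into a synthetic movie
#'
#' Each live emitter contributes a pixel-integrated isotropic 2-D Gaussian
#' of s.d. `psf_sigma` scaled to its expected photon count; Poisson noise
#' is applied to signal + background per pixel. Emitters bleach in a single
#' step with per-frame probability `bleach_prob` and stay dark afterwards.
#'
#' Coordinates: um, origin at the field's top-left; pixel `i` (0-based)
#' spans `[i * s, (i+1) * s)` um. `x_px = x_um / pixel_size`.
#'
#' @param trajs trajectory table with positions inside the field.
#' @param spec a [movie_spec()].
#' @param seed integer seed (bleaching times and noise).
#' @param n_frames frame count when `trajs` is empty (pure background
#'   movie); ignored otherwise.
#' @return list with `stack` (array `n_px x n_px x n_frames`, photon
#'   counts; first index = y/row) and `truth` (data.frame `frame`,
#'   `traj_id`, `x_px`, `y_px`, `x_um`, `y_um`, `photons`, `alive`).
#' @export
render_movie <- function(trajs, spec, seed, n_frames = 10L) {
  stopifnot(inherits(spec, "movie_spec"))
  npx <- spec$n_px
  frames <- if (nrow(trajs)) sort(unique(trajs$frame)) else 0:(n_frames - 1L)
  n_frames <- length(frames)
  if (nrow(trajs) &&
      (min(trajs$x_um) < 0 || min(trajs$y_um) < 0 ||
       max(trajs$x_um) > spec$field_size || max(trajs$y_um) > spec$field_size))
    stop("trajectories do not fit inside the field; see place_in_field()",
         call. = FALSE)

  parts <- if (nrow(trajs)) split(trajs, trajs$traj_id) else list()
  # single-step bleaching: geometric lifetime per emitter (frames survived
  # before dropping to background)
  lives <- with_seed(child_seed(seed, 0L), {
    vapply(parts, function(tr) {
      if (spec$bleach_prob <= 0) Inf else rgeom(1, spec$bleach_prob) + 1
    }, 0)
  })

  stack <- array(0, dim = c(npx, npx, n_frames))
  hw <- ceiling(4 * spec$psf_sigma / spec$pixel_size)  # PSF support half-width
  truth <- vector("list", length(parts))
  for (j in seq_along(parts)) {
    tr <- parts[[j]]
    alive <- seq_len(nrow(tr)) <= lives[j]
    truth[[j]] <- data.frame(frame = tr$frame, traj_id = tr$traj_id,
                             x_px = tr$x_um / spec$pixel_size,
                             y_px = tr$y_um / spec$pixel_size,
                             x_um = tr$x_um, y_um = tr$y_um,
                             photons = ifelse(alive, spec$photons_per_spot, 0),
                             alive = alive)
    for (r in which(alive)) {
      fi <- match(tr$frame[r], frames)
      x0 <- tr$x_um[r]; y0 <- tr$y_um[r]
      cx <- floor(x0 / spec$pixel_size); cy <- floor(y0 / spec$pixel_size)
      xs <- max(0, cx - hw):min(npx - 1, cx + hw)
      ys <- max(0, cy - hw):min(npx - 1, cy + hw)
      ex <- .psf_axis(xs * spec$pixel_size, spec$pixel_size, x0, spec$psf_sigma)
      ey <- .psf_axis(ys * spec$pixel_size, spec$pixel_size, y0, spec$psf_sigma)
      stack[ys + 1, xs + 1, fi] <- stack[ys + 1, xs + 1, fi] +
        spec$photons_per_spot * outer(ey, ex)
    }
  }
  stack <- stack + spec$background
  noisy <- with_seed(child_seed(seed, 1L),
                     array(rpois(length(stack), lambda = stack), dim = dim(stack)))
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(frame = integer(0), traj_id = integer(0), x_px = numeric(0),
               y_px = numeric(0), x_um = numeric(0), y_um = numeric(0),
               photons = numeric(0), alive = logical(0))
  rownames(truth) <- NULL
  list(stack = noisy, truth = truth)
}
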
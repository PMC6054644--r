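#' Simulate a TIRF image stack of diffraction-limited spots
#'
#' Renders each spot as an integrated symmetric 2-D Gaussian PSF at its
#' true sub-pixel center (the Gaussian is integrated over each pixel via
#' the error function, not point-sampled) on a constant background, then
#' applies Poisson shot noise. Ground-truth centers are retained for
#' validating the localization chain.
#'
#' @param trajectories list of data frames with columns \code{frame}
#'   (1-based) and \code{x_nm}, \code{y_nm} (or \code{x}, \code{y} in nm);
#'   one entry per emitter.
#' @param n_frames number of frames; default spans all trajectories.
#' @param dims image size \code{c(rows, cols)} in pixels.
#' @param psf_sigma PSF sigma in nm.
#' @param photon_rate expected photons per spot per frame (0 gives a pure
#'   background stack).
#' @param background expected background photons per pixel per frame.
#' @param pixel_size nm per pixel (default 91).
#' @param frame_interval seconds per frame.
#' @param seed optional RNG seed.
#' @return object of class \code{image_stack}: list with \code{frames}
#'   (array frame x row x col), \code{pixel_size}, \code{frame_interval},
#'   \code{psf_sigma} and \code{ground_truth} (frame, spot, x_nm, y_nm,
#'   x_px, y_px). Spots outside the field are dropped with a warning.
#' @export
simulate_image_stack <- function(trajectories, n_frames = NULL,
                                 dims = c(32L, 32L), psf_sigma = 130,
                                 photon_rate = 1000, background = 10,
                                 pixel_size = 91, frame_interval = 0.1,
                                 seed = NULL) {
  stop_if_not_positive(psf_sigma, "psf_sigma")
  stop_if_not_positive(pixel_size, "pixel_size")
  stopifnot(photon_rate >= 0, background >= 0)
  norm_traj <- lapply(trajectories, function(tr) {
    if (is.null(tr$x_nm)) {
      tr$x_nm <- tr$x
      tr$y_nm <- tr$y
    }
    tr
  })
  if (is.null(n_frames)) {
    n_frames <- max(vapply(norm_traj, function(tr) max(tr$frame),
                           numeric(1L)))
  }
  nr <- dims[1L]; nc <- dims[2L]
  s_px <- psf_sigma / pixel_size
  with_seed(seed, {
    frames <- array(0, dim = c(n_frames, nr, nc))
    gt <- list()
    n_dropped <- 0L
    for (sp in seq_along(norm_traj)) {
      tr <- norm_traj[[sp]]
      for (r in seq_len(nrow(tr))) {
        f <- tr$frame[r]
        if (f < 1L || f > n_frames) next
        x_px <- tr$x_nm[r] / pixel_size
        y_px <- tr$y_nm[r] / pixel_size
        if (x_px < 0 || x_px > nc - 1L || y_px < 0 || y_px > nr - 1L) {
          n_dropped <- n_dropped + 1L
          next
        }
        if (photon_rate > 0) {
          # integrated Gaussian: pixel i spans [i-0.5, i+0.5] around its
          # 0-based center
          px <- (0:(nc - 1L))
          py <- (0:(nr - 1L))
          wx <- stats::pnorm(px + 0.5, x_px, s_px) -
            stats::pnorm(px - 0.5, x_px, s_px)
          wy <- stats::pnorm(py + 0.5, y_px, s_px) -
            stats::pnorm(py - 0.5, y_px, s_px)
          frames[f, , ] <- frames[f, , ] + photon_rate * outer(wy, wx)
        }
        gt[[length(gt) + 1L]] <- data.frame(
          frame = f, spot = sp, x_nm = tr$x_nm[r], y_nm = tr$y_nm[r],
          x_px = x_px, y_px = y_px)
      }
    }
    if (n_dropped > 0L) {
      warning(n_dropped, " spot position(s) outside the field were dropped")
    }
    frames <- frames + background
    noisy <- array(stats::rpois(length(frames), lambda = frames),
                   dim = dim(frames))
    structure(list(frames = noisy,
                   pixel_size = pixel_size,
                   frame_interval = frame_interval,
                   psf_sigma = psf_sigma,
                   ground_truth = if (length(gt)) do.call(rbind, gt)
                   else NULL),
              class = "image_stack")
  })
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_stack> %d frame(s) of %d x %d px (%g nm/px)\n",
              d[1L], d[2L], d[3L], x$pixel_size))
  invisible(x)
}
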
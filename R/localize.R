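# Quantum-dot localization and tracking: spot detection, 2-D Gaussian PSF
# fitting, greedy nearest-neighbor linking, localization precision.
#
# Pixel convention: pixel centers at integer coordinates, 0-based, origin
# at the top-left pixel center; x runs along columns, y along rows.
# Conversion to nm is via pixel_size.

#' Detect candidate fluorescent spots in one frame
#'
#' Local maxima above a robust background threshold
#' (median + k * MAD of the frame), one square ROI per maximum.
#'
#' @param frame numeric matrix of intensities (rows = y, cols = x).
#' @param k threshold in background SDs above the median (default 5).
#' @param psf_sigma_px PSF sigma in pixels, used to size the ROI.
#' @param roi_half ROI half-width in pixels; default
#'   \code{max(3, ceiling(3 * psf_sigma_px))}.
#' @return data frame of candidates: \code{x}, \code{y} (0-based pixel
#'   coordinates of the maximum), \code{value}, \code{roi_half}.
#' @export
detect_spots <- function(frame, k = 5, psf_sigma_px = 1.3,
                         roi_half = NULL) {
  stopifnot(is.matrix(frame), length(frame) > 0L)
  if (any(frame >= .Machine$integer.max)) {
    warning("frame contains saturated pixels; proceeding")
  }
  if (is.null(roi_half)) roi_half <- max(3L, ceiling(3 * psf_sigma_px))
  bg <- stats::median(frame)
  noise <- stats::mad(frame)
  thr <- bg + k * noise
  nr <- nrow(frame); nc <- ncol(frame)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- frame
  nbr_max <- matrix(-Inf, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nbr_max <- pmax(nbr_max,
                    pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc])
  }
  # >= tolerates plateaus from integer photon counts; duplicate maxima of
  # one spot are then removed by non-maximum suppression below
  is_max <- frame >= nbr_max & frame > thr
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(data.frame(x = numeric(0), y = numeric(0), value = numeric(0),
                      roi_half = integer(0)))
  }
  cand <- data.frame(x = idx[, "col"] - 1L, y = idx[, "row"] - 1L,
                     value = frame[idx])
  cand <- cand[order(-cand$value), , drop = FALSE]
  min_sep <- roi_half
  keep <- integer(0L)
  for (i in seq_len(nrow(cand))) {
    if (!length(keep) ||
        all((cand$x[i] - cand$x[keep])^2 +
              (cand$y[i] - cand$y[keep])^2 >= min_sep^2)) {
      keep <- c(keep, i)
    }
  }
  cand <- cand[keep, , drop = FALSE]
  rownames(cand) <- NULL
  cand$roi_half <- roi_half
  cand
}

#' Fit a symmetric 2-D Gaussian to a spot's intensity profile
#'
#' Least-squares fit of
#' \deqn{I(x, y) = A \exp\left(-\frac{(x-x_0)^2 + (y-y_0)^2}{2\sigma^2}\right) + b}
#' to the ROI around a candidate spot. A circular PSF is assumed.
#'
#' @param frame intensity matrix.
#' @param x0,y0 candidate center, 0-based pixel coordinates.
#' @param roi_half ROI half-width (pixels).
#' @param pixel_size pixel size in nm (default 91), used for the nm-scale
#'   outputs.
#' @return object of class \code{spot_fit}: list with sub-pixel
#'   \code{x}, \code{y} (pixels), \code{x_nm}, \code{y_nm},
#'   \code{sigma} (nm), \code{amplitude}, \code{offset},
#'   \code{residual} (RMS residual / amplitude) and \code{converged}.
#'   Returns NULL (rejected spot) when the fit is singular.
#' @export
fit_gaussian2d <- function(frame, x0, y0, roi_half = 4L, pixel_size = 91) {
  nr <- nrow(frame); nc <- ncol(frame)
  r0 <- max(1L, round(y0) + 1L - roi_half)
  r1 <- min(nr, round(y0) + 1L + roi_half)
  c0 <- max(1L, round(x0) + 1L - roi_half)
  c1 <- min(nc, round(x0) + 1L + roi_half)
  roi <- frame[r0:r1, c0:c1, drop = FALSE]
  xs <- (c0:c1) - 1L
  ys <- (r0:r1) - 1L
  dat <- data.frame(z = as.vector(roi),
                    x = rep(xs, each = length(ys)),
                    y = rep(ys, times = length(xs)))
  b0 <- min(dat$z)
  a0 <- max(dat$z) - b0
  if (a0 <= 0) return(NULL)
  wz <- pmax(dat$z - b0, 0)
  cx <- sum(wz * dat$x) / sum(wz)
  cy <- sum(wz * dat$y) / sum(wz)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ A * exp(-((x - mx)^2 + (y - my)^2) / (2 * s^2)) + b,
      data = dat,
      start = list(A = a0, mx = cx, my = cy, s = 1.3, b = b0),
      lower = c(A = .Machine$double.eps, mx = min(xs) - 1, my = min(ys) - 1,
                s = 0.3, b = -Inf),
      upper = c(A = Inf, mx = max(xs) + 1, my = max(ys) + 1,
                s = length(xs), b = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  inside <- cf["mx"] >= min(xs) && cf["mx"] <= max(xs) &&
    cf["my"] >= min(ys) && cf["my"] <= max(ys)
  if (!inside || cf["A"] <= 0) return(NULL)
  structure(list(x = unname(cf["mx"]), y = unname(cf["my"]),
                 x_nm = unname(cf["mx"]) * pixel_size,
                 y_nm = unname(cf["my"]) * pixel_size,
                 sigma = unname(cf["s"]) * pixel_size,
                 amplitude = unname(cf["A"]),
                 offset = unname(cf["b"]),
                 residual = sqrt(mean(stats::resid(fit)^2)) /
                   unname(cf["A"]),
                 converged = TRUE),
            class = "spot_fit")
}

#' Localize all spots in an image stack
#'
#' Convenience wrapper: [detect_spots()] + [fit_gaussian2d()] per frame.
#'
#' @param stack an \code{image_stack} (see [simulate_image_stack()]) or a
#'   3-D array (frame, row, col).
#' @param k detection threshold in background SDs.
#' @param psf_sigma_px PSF sigma in pixels for detection/ROI sizing.
#' @param pixel_size nm per pixel; taken from the stack when available.
#' @return data frame of fits: \code{frame} (1-based), \code{x}, \code{y}
#'   (px), \code{x_nm}, \code{y_nm}, \code{sigma}, \code{amplitude},
#'   \code{offset}, \code{residual}.
#' @export
localize_stack <- function(stack, k = 5, psf_sigma_px = NULL,
                           pixel_size = NULL) {
  frames <- if (is.list(stack)) stack$frames else stack
  if (is.null(pixel_size)) {
    pixel_size <- if (is.list(stack)) stack$pixel_size else 91
  }
  if (is.null(psf_sigma_px)) {
    psf_sigma_px <- if (is.list(stack) && !is.null(stack$psf_sigma)) {
      stack$psf_sigma / pixel_size
    } else 1.3
  }
  out <- list()
  for (f in seq_len(dim(frames)[1L])) {
    fr <- frames[f, , ]
    cand <- detect_spots(fr, k = k, psf_sigma_px = psf_sigma_px)
    for (j in seq_len(nrow(cand))) {
      sf <- fit_gaussian2d(fr, cand$x[j], cand$y[j],
                           roi_half = cand$roi_half[j],
                           pixel_size = pixel_size)
      if (!is.null(sf)) {
        out[[length(out) + 1L]] <- data.frame(
          frame = f, x = sf$x, y = sf$y, x_nm = sf$x_nm, y_nm = sf$y_nm,
          sigma = sf$sigma, amplitude = sf$amplitude, offset = sf$offset,
          residual = sf$residual)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      x_nm = numeric(0), y_nm = numeric(0),
                      sigma = numeric(0), amplitude = numeric(0),
                      offset = numeric(0), residual = numeric(0)))
  }
  do.call(rbind, out)
}

#' Link per-frame spot fits into trajectories
#'
#' Greedy nearest-neighbor linking: in each frame, candidate fits are
#' assigned to the spatially closest open trajectory within
#' \code{max_jump}; when two candidates compete for the same trajectory
#' the closer wins, distance ties broken by the lower fit residual.
#' Unassigned fits open new trajectories; trajectories missing a frame are
#' closed (no gap closing unless \code{gap_frames > 0}). Trajectories
#' shorter than \code{min_frames} are discarded and counted.
#'
#' @param fits data frame from [localize_stack()] (needs \code{frame},
#'   \code{x_nm}, \code{y_nm}; \code{residual} used for tie-breaks).
#' @param max_jump largest per-frame displacement (nm).
#' @param min_frames minimum trajectory length in frames (default 10).
#' @param gap_frames number of consecutive missed frames tolerated
#'   (default 0).
#' @param frame_interval seconds per frame, for the \code{time} column.
#' @return list with \code{trajectories} (list of data frames with
#'   \code{frame}, \code{time}, \code{x}, \code{y} in nm) and
#'   \code{n_discarded} (trajectories dropped by the frame filter).
#' @export
link_trajectories <- function(fits, max_jump, min_frames = 10L,
                              gap_frames = 0L, frame_interval = 0.1) {
  stopifnot(nrow(fits) == 0L || !is.unsorted(fits$frame))
  open <- list()   # each: list(rows = data.frame, last_frame)
  closed <- list()
  for (f in sort(unique(fits$frame))) {
    ff <- fits[fits$frame == f, , drop = FALSE]
    # close stale trajectories
    stale <- vapply(open, function(tr) {
      f - tr$last_frame > 1L + gap_frames
    }, logical(1L))
    closed <- c(closed, open[stale])
    open <- open[!stale]
    assigned_fit <- rep(FALSE, nrow(ff))
    if (length(open) && nrow(ff)) {
      last_x <- vapply(open, function(tr) tr$x_last, numeric(1L))
      last_y <- vapply(open, function(tr) tr$y_last, numeric(1L))
      dmat <- outer(ff$x_nm, last_x, "-")^2 + outer(ff$y_nm, last_y, "-")^2
      dmat <- sqrt(dmat)
      repeat {
        dmin <- min(dmat)
        if (!is.finite(dmin) || dmin > max_jump) break
        hit <- which(dmat == dmin, arr.ind = TRUE)
        if (nrow(hit) > 1L) {  # tie: lower residual wins
          res <- ff$residual[hit[, 1L]]
          hit <- hit[which.min(res), , drop = FALSE]
        }
        i <- hit[1L, 1L]; j <- hit[1L, 2L]
        open[[j]]$rows <- rbind(open[[j]]$rows, ff[i, , drop = FALSE])
        open[[j]]$last_frame <- f
        open[[j]]$x_last <- ff$x_nm[i]
        open[[j]]$y_last <- ff$y_nm[i]
        assigned_fit[i] <- TRUE
        dmat[i, ] <- Inf
        dmat[, j] <- Inf
      }
    }
    for (i in which(!assigned_fit)) {
      open[[length(open) + 1L]] <- list(rows = ff[i, , drop = FALSE],
                                        last_frame = f,
                                        x_last = ff$x_nm[i],
                                        y_last = ff$y_nm[i])
    }
  }
  closed <- c(closed, open)
  trajs <- lapply(closed, function(tr) {
    data.frame(frame = tr$rows$frame,
               time = (tr$rows$frame - 1L) * frame_interval,
               x = tr$rows$x_nm, y = tr$rows$y_nm)
  })
  long <- vapply(trajs, nrow, integer(1L)) >= min_frames
  list(trajectories = trajs[long], n_discarded = sum(!long))
}

#' Localization precision from an immobile spot
#'
#' Pooled per-axis standard deviation of the fitted positions of an
#' immobile emitter over at least \code{min_frames} frames. A trajectory
#' showing a significant linear trend (drift larger than twice the
#' residual noise over its duration) is rejected as not immobile.
#'
#' @param trajectory data frame with \code{x}, \code{y} (nm).
#' @param min_frames minimum number of frames (default 20).
#' @return precision in nm; \code{NA} with attribute
#'   \code{"reason" = "drift"} when the immobility test fails.
#' @export
localization_precision <- function(trajectory, min_frames = 20L) {
  n <- nrow(trajectory)
  if (n < min_frames) {
    stop("need at least ", min_frames, " frames of an immobile spot",
         call. = FALSE)
  }
  t_idx <- seq_len(n)
  drift <- FALSE
  for (axis in c("x", "y")) {
    z <- trajectory[[axis]]
    fit <- stats::lm(z ~ t_idx)
    slope <- unname(stats::coef(fit)[2L])
    resid_sd <- stats::sd(stats::resid(fit))
    if (resid_sd > 0 && abs(slope) * (n - 1L) > 2 * resid_sd) {
      drift <- TRUE
    }
  }
  if (drift) {
    return(structure(NA_real_, reason = "drift"))
  }
  x <- trajectory$x; y <- trajectory$y
  sqrt((sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (2 * n - 2))
}
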
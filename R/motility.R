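# Unloaded motility observables: interpolated run length, plateau step
# detection, Michaelis-Menten velocity, runs per second, gliding-assay
# velocity filter.

#' Interpolated run length of a motility trajectory
#'
#' Arc length of the trajectory along a smoothed path. Raw frame-to-frame
#' arc length is inflated by localization noise, so the trajectory is
#' reduced to anchor points (block means of consecutive frames) spaced
#' widely enough that the expected travel between anchors dominates the
#' residual anchor noise; the polyline length through the anchors is then
#' rescaled for the half-blocks not covered at the two ends. Block size
#' starts at 5 frames and grows automatically when the noise-to-travel
#' ratio demands it.
#'
#' @param trajectory data frame with columns \code{x}, \code{y} (nm) and
#'   optionally \code{time}; frames must be consecutive.
#' @param min_frames shortest usable trajectory (default 10 frames, the
#'   standard motility filter).
#' @param block base anchor block size in frames.
#' @param noise_factor required ratio of expected anchor-to-anchor travel
#'   to anchor noise; blocks grow until it is met.
#' @param loc_noise per-axis localization noise (nm); estimated from
#'   detrended frame-to-frame differences when NULL.
#' @return run length in nm. Zero-extent trajectories return 0 with a
#'   warning.
#' @export
compute_run_length <- function(trajectory, min_frames = 10L, block = 5L,
                               noise_factor = 14, loc_noise = NULL) {
  n <- nrow(trajectory)
  if (n < min_frames) {
    stop("trajectory has fewer than ", min_frames, " frames", call. = FALSE)
  }
  x <- trajectory$x; y <- trajectory$y
  span <- sqrt((x[n] - x[1L])^2 + (y[n] - y[1L])^2)
  if (is.null(loc_noise)) {
    # second differences cancel linear motion; var = 6 sigma^2
    loc_noise <- stats::mad(c(diff(x, differences = 2L),
                              diff(y, differences = 2L))) / sqrt(6)
  }
  if (span < max(4 * loc_noise, .Machine$double.eps)) {
    warning("zero-extent trajectory; run length reported as 0")
    return(structure(0, degenerate = TRUE))
  }
  d_frame <- span / (n - 1L)   # expected per-frame travel
  m <- block
  if (loc_noise > 0) {
    # anchor spacing m*d_frame must exceed noise_factor * sigma * sqrt(2/m)
    m_req <- (noise_factor * loc_noise * sqrt(2) / d_frame)^(2 / 3)
    m <- max(block, ceiling(m_req))
  }
  m <- min(m, floor(n / 2))
  if (m < 1L) m <- 1L
  blocks <- split(seq_len(n), ceiling(seq_len(n) / m))
  cx <- vapply(blocks, function(i) mean(x[i]), numeric(1L))
  cy <- vapply(blocks, function(i) mean(y[i]), numeric(1L))
  if (length(cx) < 2L) return(span)
  # the raw endpoints bracket the anchor chain so the half-blocks at the
  # two ends are not lost (their noise affects only two short segments)
  px <- c(x[1L], cx, x[n])
  py <- c(y[1L], cy, y[n])
  wts <- c(1, lengths(blocks), 1)
  # anchors separated by less than their joint noise carry no evidence of
  # motion; summing |noise| over them would inflate the arc length (worst
  # on stepped traces whose dwells span several blocks), so statistically
  # indistinguishable anchors are pooled before the polyline is measured
  if (loc_noise > 0) {
    sig2 <- loc_noise^2
    gx <- px[1L] * wts[1L]; gy <- py[1L] * wts[1L]; gw <- wts[1L]
    ox <- oy <- numeric(0L)
    for (j in 2:length(px)) {
      tol <- 4 * sqrt(sig2 / gw + sig2 / wts[j])
      d <- sqrt((px[j] - gx / gw)^2 + (py[j] - gy / gw)^2)
      if (d < tol) {
        gx <- gx + px[j] * wts[j]; gy <- gy + py[j] * wts[j]
        gw <- gw + wts[j]
      } else {
        ox <- c(ox, gx / gw); oy <- c(oy, gy / gw)
        gx <- px[j] * wts[j]; gy <- py[j] * wts[j]; gw <- wts[j]
      }
    }
    px <- c(ox, gx / gw); py <- c(oy, gy / gw)
    if (length(px) < 2L) return(span)
  }
  sum(sqrt(diff(px)^2 + diff(py)^2))
}

# default penalty (in units of sigma^2) for the plateau change-point
# detector: just above the 99th percentile of the maximal RSS gain on
# pure-noise traces, which simulation shows to be nearly flat (~15) over
# trace lengths of 100-3000 frames when sigma is estimated from first
# differences (see the methods vignette). Keeps false plateau splits
# below ~1% per trace.
step_penalty_default <- function(n) 16

#' Detect discrete steps in an unloaded stepping trajectory
#'
#' Change-point segmentation of a low-ATP trajectory into plateaus by
#' recursive binary splitting: a split is accepted while the residual
#' sum-of-squares gain exceeds \code{penalty * sigma^2}, with the noise
#' level \code{sigma} estimated robustly from frame-to-frame differences.
#' The 2-D trajectory is first projected on its principal axis. Step sizes
#' are differences of adjacent plateau means (signed along the direction
#' of net motion).
#'
#' @param trajectory data frame with \code{x}, \code{y} (nm) and
#'   \code{time} (s), or a numeric vector of 1-D positions.
#' @param penalty RSS-gain acceptance threshold in units of the noise
#'   variance; the default grows with trace length and is calibrated so
#'   that fewer than 1\% of pure-noise traces yield any step.
#' @param min_seg shortest plateau (frames).
#' @param sigma noise SD (nm); estimated when NULL.
#' @return data frame of steps: \code{index} (frame of the new plateau),
#'   \code{time} (s, when available), \code{size} (nm, signed).
#' @seealso [summarize_steps()]
#' @export
detect_steps_unloaded <- function(trajectory, penalty = NULL, min_seg = 3L,
                                  sigma = NULL) {
  if (is.data.frame(trajectory)) {
    xy <- cbind(trajectory$x, trajectory$y)
    xy <- sweep(xy, 2L, colMeans(xy))
    v <- svd(xy, nu = 0L, nv = 1L)$v[, 1L]
    # orient the axis along net motion
    if (sum(xy[nrow(xy), ] * v) < sum(xy[1L, ] * v)) v <- -v
    s <- as.numeric(xy %*% v)
    times <- trajectory$time
  } else {
    s <- as.numeric(trajectory)
    times <- NULL
  }
  n <- length(s)
  empty <- data.frame(index = integer(0), time = numeric(0),
                      size = numeric(0))
  if (n < 2L * min_seg + 1L) return(empty)
  if (is.null(sigma)) sigma <- stats::mad(diff(s)) / sqrt(2)
  if (!is.finite(sigma) || sigma <= 0) sigma <- stats::sd(s) / 10
  if (is.null(penalty)) penalty <- step_penalty_default(n)
  thr <- penalty * sigma^2
  cps <- binseg_split(s, 1L, n, min_seg, thr)
  if (!length(cps)) return(empty)
  cps <- sort(cps)
  bounds <- c(1L, cps, n + 1L)
  means <- vapply(seq_len(length(bounds) - 1L), function(j) {
    mean(s[bounds[j]:(bounds[j + 1L] - 1L)])
  }, numeric(1L))
  plat_len <- diff(bounds)
  data.frame(index = cps,
             time = if (!is.null(times)) times[cps] else NA_real_,
             size = diff(means),
             dwell_before = plat_len[-length(plat_len)],
             dwell_after = plat_len[-1L])
}

# recursive binary segmentation on s[a..b]; returns change-point indices
# (first frame of the right segment). O(n) per candidate split via cumsums.
binseg_split <- function(s, a, b, min_seg, thr) {
  n <- b - a + 1L
  if (n < 2L * min_seg) return(integer(0))
  x <- s[a:b]
  cs <- cumsum(x)
  tot <- cs[n]
  k <- seq.int(min_seg, n - min_seg)   # left segment length
  # RSS gain of splitting after k elements
  gain <- cs[k]^2 / k + (tot - cs[k])^2 / (n - k) - tot^2 / n
  j <- which.max(gain)
  if (gain[j] <= thr) return(integer(0))
  split_at <- a + k[j]                 # first index of right segment
  c(binseg_split(s, a, split_at - 1L, min_seg, thr),
    split_at,
    binseg_split(s, split_at, b, min_seg, thr))
}

#' Summarize detected step sizes
#'
#' Mean and s.e.m. of detected step sizes over well-isolated stepping
#' events, mirroring the manual isolation of clean steps: a step enters
#' the average only when (i) its amplitude does not exceed
#' \code{single_max} (larger jumps are unresolved multiple steps) and
#' (ii) the plateaus on both sides last at least \code{min_dwell} frames
#' (steps in rapid succession are localized too poorly for an unbiased
#' amplitude).
#'
#' @param steps data frame from [detect_steps_unloaded()] (needs
#'   \code{size}; \code{dwell_before}/\code{dwell_after} used when
#'   present).
#' @param single_max amplitude (nm) above which a detected step is treated
#'   as an unresolved multiple (default 54 = 1.5 lattice repeats).
#' @param min_dwell shortest flanking plateau (frames) for a clean step.
#' @return list with \code{mean}, \code{sem}, \code{n}, \code{n_excluded}.
#' @export
summarize_steps <- function(steps, single_max = 54, min_dwell = 6L) {
  sz <- steps$size
  keep <- abs(sz) <= single_max
  if (!is.null(steps$dwell_before)) {
    keep <- keep & steps$dwell_before >= min_dwell &
      steps$dwell_after >= min_dwell
  }
  list(mean = mean(sz[keep]), sem = sem(sz[keep]),
       n = sum(keep), n_excluded = sum(!keep))
}

#' Observed frequency of processive runs
#'
#' @param n_runs number of runs observed (trajectories longer than the
#'   minimum frame filter).
#' @param total_time total acquisition time (s) across fields of view.
#' @return runs per second.
#' @export
runs_per_second <- function(n_runs, total_time) {
  stop_if_not_positive(total_time, "total_time")
  stopifnot(n_runs >= 0)
  n_runs / total_time
}

#' Gliding-assay velocity-dispersion filter
#'
#' Partitions per-filament velocity series by the relative velocity
#' dispersion rule: a filament is kept iff
#' \code{sd(v)/mean(v) <= threshold} (boundary inclusive). Filaments with
#' non-positive mean velocity are excluded and flagged.
#'
#' @param velocities list of per-filament instantaneous velocity vectors
#'   (nm/s).
#' @param threshold largest admissible sd/mean ratio (default 0.33).
#' @return list with \code{kept} and \code{excluded} index vectors and a
#'   data frame \code{summary} (mean, sd, ratio, kept, reason).
#' @export
filter_gliding_velocities <- function(velocities, threshold = 0.33) {
  stopifnot(is.list(velocities))
  summ <- do.call(rbind, lapply(seq_along(velocities), function(i) {
    v <- velocities[[i]]
    m <- mean(v); s <- stats::sd(v)
    if (!is.finite(m) || m <= 0) {
      data.frame(filament = i, mean = m, sd = s, ratio = NA_real_,
                 kept = FALSE, reason = "non-positive mean velocity")
    } else {
      r <- s / m
      data.frame(filament = i, mean = m, sd = s, ratio = r,
                 kept = r <= threshold,
                 reason = ifelse(r <= threshold, "",
                                 "velocity dispersion above threshold"))
    }
  }))
  list(kept = summ$filament[summ$kept],
       excluded = summ$filament[!summ$kept],
       summary = summ)
}
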
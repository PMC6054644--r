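# Force-clamp record analysis: velocity-threshold event detection,
# bidirectional step detection within runs, run assembly, per-force-bin
# statistics.

#' Sliding-window velocity estimate of a position record
#'
#' Centered linear-regression slope of position over a window of
#' \code{window} samples, evaluated at every sample (edges are NA). This is
#' the statistic all event and step detection thresholds act on.
#'
#' @param position position samples (nm).
#' @param dt sample interval (s).
#' @param window window length in samples (>= 3).
#' @return numeric vector of velocities (nm/s), NA near the edges.
#' @export
sliding_velocity <- function(position, dt, window) {
  w <- as.integer(window)
  if (w < 3L) stop("window must span at least 3 samples", call. = FALSE)
  i <- seq_len(w) - (w + 1) / 2
  kern <- i / (sum(i^2) * dt)
  as.numeric(stats::filter(position, rev(kern), method = "convolution",
                           sides = 2))
}

# window length in samples from a window duration in seconds
window_samples <- function(window_s, dt) {
  max(3L, as.integer(round(window_s / dt)))
}

#' Detect motor attachment events in a force-clamp record
#'
#' While no motor is attached the clamped dumbbell moves at the drag
#' velocity; attachment stops it. Events are intervals where the magnitude
#' of the sliding-window velocity stays below \code{velocity_threshold}.
#' Hysteresis against chatter: brief above-threshold excursions shorter
#' than \code{spike_max} (e.g. the velocity transient of a step) are
#' absorbed into the surrounding event, and candidate events shorter than
#' \code{min_duration} are discarded.
#'
#' @param record a \code{position_record} (or a list with \code{position}
#'   and \code{dt}).
#' @param velocity_threshold velocity threshold (nm/s); see
#'   [calibrate_threshold()]. Defaults to a quarter of the configured drag
#'   velocity when the record carries its configuration.
#' @param window sliding window duration (s), default 5 ms (long enough
#'   that velocity noise stays well below the drag velocity).
#' @param min_duration minimum event duration (s); default 3 windows.
#' @param spike_max longest above-threshold excursion absorbed within an
#'   event (s); default 2 windows.
#' @return data frame with one row per event: sample indices
#'   \code{start}, \code{end} and times \code{t_start}, \code{t_end}.
#' @export
detect_events <- function(record, velocity_threshold = NULL,
                          window = 0.005, min_duration = NULL,
                          spike_max = NULL) {
  pos <- record$position
  dt <- record$dt
  if (is.null(pos)) stop("record has no rendered samples", call. = FALSE)
  w <- window_samples(window, dt)
  if (is.null(velocity_threshold)) {
    if (is.null(record$config)) {
      stop("velocity_threshold is required when the record carries no ",
           "configuration; see calibrate_threshold()", call. = FALSE)
    }
    velocity_threshold <- record$config$drag_velocity / 4
  }
  if (is.null(min_duration)) min_duration <- 3 * w * dt
  if (is.null(spike_max)) spike_max <- 2 * w * dt
  vel <- sliding_velocity(pos, dt, w)
  below <- !is.na(vel) & abs(vel) < velocity_threshold
  r <- rle(below)
  # absorb short above-threshold spikes flanked by below-threshold stretches
  spike_n <- max(1L, round(spike_max / dt))
  nr <- length(r$lengths)
  if (nr >= 3L) {
    for (k in 2:(nr - 1L)) {
      if (!r$values[k] && r$lengths[k] <= spike_n &&
          r$values[k - 1L] && r$values[k + 1L]) {
        r$values[k] <- TRUE
      }
    }
  }
  below <- inverse.rle(r)
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  min_n <- max(1L, round(min_duration / dt))
  keep <- r$values & r$lengths >= min_n
  out <- data.frame(start = starts[keep], end = ends[keep])
  out$t_start <- (out$start - 1L) * dt
  out$t_end <- (out$end - 1L) * dt
  out
}

#' Calibrate the event-detection velocity threshold on motor-free records
#'
#' Chooses the largest velocity threshold whose empirical false-event rate
#' on motor-free records (records known to contain no attachment) does not
#' exceed \code{target_false_rate}. The false-event rate is the fraction of
#' records on which [detect_events()] reports at least one event. Larger
#' thresholds are more sensitive to genuine attachments but more easily
#' fooled by noise, so the calibrated threshold maximizes sensitivity
#' subject to the false-event budget.
#'
#' @param records list of motor-free \code{position_record}s at the
#'   experimental noise and oscillation settings (>= 100 recommended).
#' @param target_false_rate admissible fraction of records with a spurious
#'   event (default 0.01).
#' @param window sliding window duration (s) passed to [detect_events()].
#' @param n_grid number of candidate thresholds (geometric grid up to the
#'   drag velocity).
#' @param ... further arguments passed to [detect_events()].
#' @return list with \code{threshold} (nm/s), \code{false_rate} achieved at
#'   it, and the full \code{grid} of (threshold, false_rate) pairs.
#' @export
calibrate_threshold <- function(records, target_false_rate = 0.01,
                                window = 0.005, n_grid = 25L, ...) {
  stopifnot(length(records) >= 1L)
  drag <- records[[1L]]$config$drag_velocity
  grid <- exp(seq(log(drag / 500), log(drag * 0.9), length.out = n_grid))
  rate_at <- function(th) {
    mean(vapply(records, function(r) {
      nrow(detect_events(r, velocity_threshold = th, window = window,
                         ...)) > 0L
    }, logical(1L)))
  }
  rates <- vapply(grid, rate_at, numeric(1L))
  ok <- rates <= target_false_rate
  if (!any(ok)) {
    stop(sprintf(paste0("false-event target %.3g unattainable: smallest ",
                        "achievable rate on this grid is %.3g"),
                 target_false_rate, min(rates)), call. = FALSE)
  }
  i <- max(which(ok))
  list(threshold = grid[i], false_rate = rates[i],
       grid = data.frame(threshold = grid, false_rate = rates))
}

#' Detect forward and backward steps within one attachment event
#'
#' Steps appear as brief velocity transients inside an otherwise stationary
#' attached segment. Transitions are intervals where the sliding-window
#' velocity magnitude exceeds \code{step_threshold} in either direction;
#' transitions closer than \code{merge_gap} are merged (two steps within
#' the detector's time resolution are reported as one, which is why run
#' assembly caps step sizes at 90 nm). Plateau positions are the sample
#' means between transitions, excluding half a window margin, and the step
#' size is the difference of adjacent plateau means (signed toward the
#' plus end).
#'
#' @param record a \code{position_record}.
#' @param start,end sample indices bounding the segment (from
#'   [detect_events()]).
#' @param window sliding window duration (s), default 2 ms.
#' @param step_threshold velocity threshold (nm/s) for a step transient;
#'   default \code{NULL} uses 6 robust SDs of the within-segment velocity,
#'   with a floor of a quarter step per window.
#' @param merge_gap transitions separated by less than this (s) are merged
#'   (default 3 ms, the run-assembly time resolution).
#' @param min_plateau shortest usable plateau (s); default one window.
#' @return data frame of steps: \code{time} (s), \code{size} (nm, signed),
#'   \code{direction}, \code{dwell_before} (s), plateau means
#'   \code{level_before}, \code{level_after}.
#' @export
detect_steps_in_run <- function(record, start, end, window = 0.002,
                                step_threshold = NULL, merge_gap = 0.003,
                                min_plateau = NULL) {
  pos <- record$position
  dt <- record$dt
  w <- window_samples(window, dt)
  seg <- pos[start:end]
  n <- length(seg)
  empty <- data.frame(time = numeric(0), size = numeric(0),
                      direction = character(0), dwell_before = numeric(0),
                      level_before = numeric(0), level_after = numeric(0))
  if (n < 2L * w) return(empty)
  vel <- sliding_velocity(seg, dt, w)
  if (is.null(step_threshold)) {
    sig_v <- stats::mad(vel, na.rm = TRUE)
    floor_th <- 0.25 * 36 / (w * dt)
    step_threshold <- max(6 * sig_v, floor_th)
  }
  above <- !is.na(vel) & abs(vel) > step_threshold
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tr <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge transitions within the detector time resolution
  gap_n <- max(1L, round(merge_gap / dt))
  if (nrow(tr) > 1L) {
    merged <- tr[1L, , drop = FALSE]
    for (k in 2:nrow(tr)) {
      if (tr$start[k] - merged$end[nrow(merged)] < gap_n) {
        merged$end[nrow(merged)] <- tr$end[k]
      } else {
        merged <- rbind(merged, tr[k, ])
      }
    }
    tr <- merged
  }
  if (is.null(min_plateau)) min_plateau <- w * dt
  margin <- ceiling(w / 2)
  bounds <- c(1L, nrow(tr) + 1L)
  # plateau j lies between transition j-1 and transition j
  plat_start <- c(1L, tr$end + margin)
  plat_end <- c(tr$start - margin, n)
  plat_mean <- rep(NA_real_, length(plat_start))
  ok <- plat_end - plat_start + 1L >= max(2L, round(min_plateau / dt))
  for (j in which(ok)) {
    plat_mean[j] <- mean(seg[plat_start[j]:plat_end[j]])
  }
  # step time: extremal velocity within the transition
  t_step <- vapply(seq_len(nrow(tr)), function(k) {
    idx <- tr$start[k]:tr$end[k]
    idx[which.max(abs(vel[idx]))]
  }, numeric(1L))
  size <- plat_mean[-1L] - plat_mean[-length(plat_mean)]
  keep <- is.finite(size)
  if (!any(keep)) return(empty)
  t_abs <- (start - 1L + t_step[keep] - 1L) * dt
  data.frame(time = t_abs,
             size = size[keep],
             direction = ifelse(size[keep] >= 0, "forward", "backward"),
             dwell_before = c(t_abs[1L] - (start - 1L) * dt,
                              diff(t_abs)),
             level_before = plat_mean[-length(plat_mean)][keep],
             level_after = plat_mean[-1L][keep])
}

#' Group detected steps into runs by the time/amplitude assembly rule
#'
#' Greedy left-to-right grouping of a time-ordered step list: a step joins
#' the current run iff the interval since the previous step is shorter
#' than \code{gap_max} and its amplitude is below \code{step_max}; a step
#' violating either rule starts a new run. The amplitude cap exists
#' because two steps falling within the detector's time resolution are
#' measured as one larger step and must not be split across runs.
#'
#' @param steps data frame with columns \code{time} (s) and \code{size}
#'   (nm), time-ordered.
#' @param gap_max largest inter-step interval within one run (s).
#' @param step_max largest step amplitude within one run (nm).
#' @return the \code{steps} data frame with an added \code{run_id} column.
#' @export
assemble_runs <- function(steps, gap_max = 0.003, step_max = 90) {
  if (is.null(steps) || nrow(steps) == 0L) {
    return(cbind(if (is.null(steps)) data.frame(time = numeric(0),
                                                size = numeric(0))
                 else steps,
                 run_id = integer(0)))
  }
  stopifnot(!is.unsorted(steps$time))
  run_id <- integer(nrow(steps))
  run_id[1L] <- 1L
  current <- 1L
  for (k in seq_len(nrow(steps))[-1L]) {
    new_run <- (steps$time[k] - steps$time[k - 1L]) >= gap_max ||
      abs(steps$size[k]) >= step_max
    if (new_run) current <- current + 1L
    run_id[k] <- current
  }
  cbind(steps, run_id = run_id)
}

#' Full detection chain for a force-clamp record
#'
#' Runs [detect_events()] and [detect_steps_in_run()] and assembles one run
#' per attachment event (splitting at steps above \code{step_max}, per the
#' run-assembly amplitude rule). Per run: start/end time and position
#' (plateau means), signed run length toward the plus end, duration
#' (including the final dwell before detachment), velocity, the signed
#' force label (assistive negative), and an edge-truncation flag.
#'
#' @param record a \code{position_record}.
#' @param velocity_threshold threshold for [detect_events()] (nm/s).
#' @param event_window,step_window window durations (s) for event and step
#'   detection.
#' @param step_threshold optional explicit step threshold (nm/s).
#' @param step_max amplitude cap for run assembly (nm).
#' @param edge_tol distance from a window edge (nm) within which a run end
#'   is flagged as truncated.
#' @param ... further arguments to [detect_events()].
#' @return list with data frames \code{runs} (run_id, t_start, t_end,
#'   pos_start, pos_end, run_length, duration, velocity, force, n_fwd,
#'   n_bwd, truncated) and \code{steps} (run_id plus the
#'   [detect_steps_in_run()] columns).
#' @export
analyze_record <- function(record, velocity_threshold = NULL,
                           event_window = 0.005, step_window = 0.002,
                           step_threshold = NULL, step_max = 90,
                           edge_tol = 5, ...) {
  ev <- detect_events(record, velocity_threshold = velocity_threshold,
                      window = event_window, ...)
  D <- if (!is.null(record$config)) record$config$oscillation_range else NA
  runs <- list(); steps_out <- list(); rid <- 0L
  for (k in seq_len(nrow(ev))) {
    st <- detect_steps_in_run(record, ev$start[k], ev$end[k],
                              window = step_window,
                              step_threshold = step_threshold)
    # force label: channel is the push direction along +x; motor motion is
    # +x, so channel +F means assistive, labelled -F
    mid <- (ev$start[k] + ev$end[k]) %/% 2L
    f_signed <- -record$force[mid]
    # split the event at oversized steps (amplitude assembly rule)
    # an oversized step starts a new run (amplitude assembly rule)
    groups <- if (nrow(st) > 0L) {
      big <- abs(st$size) >= step_max
      cumsum(big) + as.integer(!big[1L])
    } else integer(0)
    seg_pos <- function(i0, i1) {
      mean(record$position[i0:i1])
    }
    w <- window_samples(step_window, record$dt)
    if (nrow(st) == 0L) {
      rid <- rid + 1L
      p0 <- seg_pos(ev$start[k], min(ev$end[k], ev$start[k] + 4L * w))
      p1 <- seg_pos(max(ev$start[k], ev$end[k] - 4L * w), ev$end[k])
      runs[[rid]] <- data.frame(
        run_id = rid, t_start = ev$t_start[k], t_end = ev$t_end[k],
        pos_start = p0, pos_end = p1, force = f_signed,
        n_fwd = 0L, n_bwd = 0L)
    } else {
      for (g in unique(groups)) {
        rid <- rid + 1L
        idx <- which(groups == g)
        sg <- st[idx, , drop = FALSE]
        t0 <- if (g == min(groups)) ev$t_start[k] else sg$time[1L]
        t1 <- if (g == max(groups)) ev$t_end[k] else
          st$time[idx[length(idx)] + 1L]
        runs[[rid]] <- data.frame(
          run_id = rid, t_start = t0, t_end = t1,
          pos_start = sg$level_before[1L],
          pos_end = sg$level_after[nrow(sg)],
          force = f_signed,
          n_fwd = sum(sg$size >= 0), n_bwd = sum(sg$size < 0))
        steps_out[[rid]] <- cbind(run_id = rid, sg)
      }
    }
  }
  runs <- if (length(runs)) do.call(rbind, runs) else
    data.frame(run_id = integer(0), t_start = numeric(0),
               t_end = numeric(0), pos_start = numeric(0),
               pos_end = numeric(0), force = numeric(0),
               n_fwd = integer(0), n_bwd = integer(0))
  if (nrow(runs)) {
    runs$run_length <- runs$pos_end - runs$pos_start
    runs$duration <- runs$t_end - runs$t_start
    runs$velocity <- runs$run_length / runs$duration
    runs$truncated <- if (is.finite(D)) {
      # truncation parks the dumbbell at the edge the force pushes toward:
      # assistive (label < 0) pushes +x toward D, resistive toward 0
      (runs$force < 0 & abs(runs$pos_end - D) <= edge_tol) |
        (runs$force > 0 & abs(runs$pos_end - 0) <= edge_tol)
    } else FALSE
  } else {
    runs$run_length <- runs$duration <- runs$velocity <- numeric(0)
    runs$truncated <- logical(0)
  }
  steps <- if (length(steps_out)) do.call(rbind, steps_out) else
    data.frame(run_id = integer(0), time = numeric(0), size = numeric(0),
               direction = character(0), dwell_before = numeric(0),
               level_before = numeric(0), level_after = numeric(0))
  list(runs = runs, steps = steps)
}

#' Per-force-bin run and step statistics
#'
#' Aggregates detected runs and steps into signed-force bins: run counts,
#' mean run length, duration and velocity with standard errors, the
#' detachment rate \eqn{k = 1/\langle\tau\rangle} with its propagated
#' error \eqn{\sigma_k = \sigma_\tau \langle\tau\rangle^{-2}}, mean signed,
#' forward and backward step sizes, forward/backward counts and their
#' ratio, and stepping rates (counts per total attached time in the bin).
#'
#' @param runs run data frame from [analyze_record()] (or the simulator's
#'   ground truth with columns \code{force}, \code{run_length} or
#'   pos_start/pos_end, \code{duration} or t_start/t_end).
#' @param steps optional step data frame with \code{run_id} and \code{size}.
#' @param bin_edges signed force bin edges (pN), e.g.
#'   \code{seq(-3, 3, by = 0.4)}.
#' @param drop_truncated exclude edge-truncated runs from run-length and
#'   duration means (they are corrected downstream via
#'   [correct_run_length()] instead when kept).
#' @return data frame, one row per non-empty bin. Runs outside the edges
#'   are counted in attribute \code{"n_out_of_range"}. The ratio
#'   \code{ratio_fwd_bwd} is NA (flagged) when no backward steps fell in
#'   the bin.
#' @export
bin_statistics <- function(runs, steps = NULL, bin_edges,
                           drop_truncated = FALSE) {
  stopifnot(nrow(runs) > 0L, length(bin_edges) >= 2L)
  if (is.null(runs$run_length)) {
    runs$run_length <- runs$pos_end - runs$pos_start
  }
  if (is.null(runs$duration)) runs$duration <- runs$t_end - runs$t_start
  if (is.null(runs$truncated)) runs$truncated <- FALSE
  bin <- findInterval(runs$force, bin_edges, rightmost.closed = TRUE)
  in_range <- bin >= 1L & bin <= length(bin_edges) - 1L
  out <- lapply(sort(unique(bin[in_range])), function(b) {
    sel <- in_range & bin == b
    rr <- runs[sel, , drop = FALSE]
    use <- if (drop_truncated) !rr$truncated else rep(TRUE, nrow(rr))
    if (!any(use)) return(NULL)
    tau <- rr$duration[use]
    st <- if (!is.null(steps)) {
      steps[steps$run_id %in% rr$run_id, , drop = FALSE]
    } else NULL
    n_fwd <- if (!is.null(st)) sum(st$size >= 0) else sum(rr$n_fwd)
    n_bwd <- if (!is.null(st)) sum(st$size < 0) else sum(rr$n_bwd)
    t_attached <- sum(rr$duration)
    mean_tau <- mean(tau)
    sem_tau <- sem(tau)
    data.frame(
      force_center = (bin_edges[b] + bin_edges[b + 1L]) / 2,
      n_runs = nrow(rr),
      n_truncated = sum(rr$truncated),
      mean_run_length = mean(rr$run_length[use]),
      sem_run_length = sem(rr$run_length[use]),
      mean_duration = mean_tau,
      sem_duration = sem_tau,
      detachment_rate = 1 / mean_tau,
      sem_detachment_rate = sem_tau / mean_tau^2,
      mean_velocity = mean(rr$velocity[use]),
      sem_velocity = sem(rr$velocity[use]),
      mean_step = if (!is.null(st) && nrow(st)) mean(st$size) else NA_real_,
      sem_step = if (!is.null(st) && nrow(st)) sem(st$size) else NA_real_,
      mean_step_fwd = if (!is.null(st) && n_fwd)
        mean(st$size[st$size >= 0]) else NA_real_,
      mean_step_bwd = if (!is.null(st) && n_bwd)
        mean(st$size[st$size < 0]) else NA_real_,
      n_fwd = n_fwd, n_bwd = n_bwd,
      ratio_fwd_bwd = if (n_bwd > 0) n_fwd / n_bwd else NA_real_,
      stepping_rate_fwd = n_fwd / t_attached,
      stepping_rate_bwd = n_bwd / t_attached)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  n_out <- sum(!in_range)
  if (n_out > 0L) {
    warning(n_out, " run(s) outside the bin range were left unbinned")
  }
  attr(out, "n_out_of_range") <- n_out
  out
}
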
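#' Simulate one processive run as a continuous-time Markov realization
#'
#' Gillespie realization of the three competing exponential clocks of a
#' [motor_model()] at a fixed signed force: forward step (+\code{step_fwd}),
#' backward step (-\code{step_bwd}) and detachment. The realization starts
#' with an attachment event and ends at detachment or at \code{max_duration},
#' whichever comes first.
#'
#' @param model a [motor_model()].
#' @param force signed force in pN (assistive < 0, resistive > 0).
#' @param max_duration cap on the attached duration (s).
#' @param seed optional RNG seed for reproducibility.
#' @param t0,pos0 time (s) and position (nm) of the attachment event.
#' @return A \code{state_trajectory}: data frame with columns \code{time}
#'   (s), \code{kind} (\code{attach}, \code{step_fwd}, \code{step_bwd},
#'   \code{detach}) and \code{position} (nm), carrying attributes
#'   \code{force} and \code{censored} (TRUE when ended by
#'   \code{max_duration} rather than detachment).
#' @export
simulate_stepping <- function(model, force, max_duration = Inf, seed = NULL,
                              t0 = 0, pos0 = 0) {
  stopifnot(inherits(model, "motor_model"))
  rates <- stepping_rates(model, force)
  with_seed(seed, {
    sim_run_events(model, force, rates, t0 = t0, pos0 = pos0,
                   t_max = t0 + max_duration)
  })
}

# Core run sampler shared by simulate_stepping() and simulate_clamp_record().
# Truncation geometry: when `window` is given (c(lo, hi)) and `trunc_dir`
# is +1/-1, a step that carries the position past the corresponding edge
# terminates the run there with censored = TRUE (edge-censored run).
sim_run_events <- function(model, force, rates, t0, pos0, t_max,
                           window = NULL, trunc_dir = 0L) {
  k_tot <- rates$k_fwd + rates$k_bwd + rates$k_det
  times <- t0
  kinds <- "attach"
  pos <- pos0
  t <- t0
  p <- pos0
  censored <- FALSE
  truncated <- FALSE
  f <- abs(force)
  p_short <- if (model$short_step_prob_scale > 0) {
    stats::plogis(model$short_step_prob_scale * (f - 1))
  } else 0
  repeat {
    dt <- stats::rexp(1L, k_tot)
    if (t + dt > t_max) {
      t <- t_max
      censored <- TRUE
      break
    }
    t <- t + dt
    u <- stats::runif(1L) * k_tot
    if (u < rates$k_det) {
      times <- c(times, t); kinds <- c(kinds, "detach"); pos <- c(pos, p)
      break
    }
    fwd <- u < rates$k_det + rates$k_fwd
    size <- if (fwd) {
      if (p_short > 0 && force > 0 && stats::runif(1L) < p_short) 20 else model$step_fwd
    } else {
      -(if (p_short > 0 && force < 0 && stats::runif(1L) < p_short) 15 else model$step_bwd)
    }
    p_new <- p + size
    if (!is.null(window) && trunc_dir != 0L) {
      edge <- if (trunc_dir > 0L) window[2L] else window[1L]
      hit <- if (trunc_dir > 0L) p_new >= edge else p_new <= edge
      if (hit) {
        p <- edge
        times <- c(times, t)
        kinds <- c(kinds, if (fwd) "step_fwd" else "step_bwd")
        pos <- c(pos, p)
        censored <- TRUE
        truncated <- TRUE
        break
      }
    }
    p <- p_new
    times <- c(times, t)
    kinds <- c(kinds, if (fwd) "step_fwd" else "step_bwd")
    pos <- c(pos, p)
  }
  if (!censored || truncated) {
    # edge-censored runs also end in a (truncated) detach marker
    if (truncated) {
      times <- c(times, t); kinds <- c(kinds, "detach"); pos <- c(pos, p)
    }
  } else {
    times <- c(times, t); kinds <- c(kinds, "detach"); pos <- c(pos, p)
  }
  structure(data.frame(time = times, kind = kinds, position = pos,
                       stringsAsFactors = FALSE),
            force = force, censored = censored, truncated = truncated,
            class = c("state_trajectory", "data.frame"))
}

#' @export
print.state_trajectory <- function(x, ...) {
  n_steps <- sum(x$kind %in% c("step_fwd", "step_bwd"))
  cat(sprintf("<state_trajectory> %d steps, %.4g s, force %.3g pN%s\n",
              n_steps, max(x$time) - min(x$time), attr(x, "force"),
              if (isTRUE(attr(x, "truncated"))) " (edge-truncated)" else ""))
  NextMethod()
}

#' Simulate an ultrafast force-clamp position record
#'
#' Generates a dumbbell position record with the full measurement geometry:
#' while no motor is attached the clamped force sweeps the dumbbell in a
#' triangular wave across the oscillation window \code{[0, D]}, the force
#' sign flipping at the edges; after an exponential waiting time the motor
#' attaches at the current dumbbell position and the record follows its
#' stepping staircase at the signed force set by the oscillation phase
#' (force pushing with the motor = assistive, labelled negative). A run
#' that carries the dumbbell to the window edge toward which the force
#' points is terminated there (edge truncation, the censoring corrected by
#' [correct_run_length()]). Gaussian position noise is added per sample.
#'
#' @param model a [motor_model()].
#' @param cfg a [clamp_config()].
#' @param duration record length (s).
#' @param seed optional RNG seed.
#' @param render if FALSE, skip sampling the record and return the
#'   event-level ground truth only (fast path for large ensembles).
#' @return object of class \code{position_record}: list with \code{position}
#'   (nm, noisy samples), \code{force} (signed pN per sample, the direction
#'   the clamp pushes along +x), \code{dt}, \code{config}, \code{model} and
#'   \code{truth}. \code{truth$runs} is a data frame of generating runs
#'   (start/end time and position, signed force label, truncation flag,
#'   forward/backward step counts); \code{truth$steps} the generating steps;
#'   \code{truth$events} the full event list.
#' @export
simulate_clamp_record <- function(model, cfg, duration = 5, seed = NULL,
                                  render = TRUE) {
  stopifnot(inherits(model, "motor_model"), inherits(cfg, "clamp_config"))
  D <- cfg$oscillation_range
  if (D <= model$step_fwd) {
    stop("oscillation_range must exceed the forward step size; no run ",
         "would be observable", call. = FALSE)
  }
  with_seed(seed, {
    v <- cfg$drag_velocity
    Fm <- cfg$force_magnitude
    t <- 0; p <- 0; dir <- 1L
    seg_t0 <- seg_t1 <- seg_p0 <- seg_p1 <- seg_f <- numeric(0L)
    add_seg <- function(t0, t1, p0, p1, f) {
      if (t1 > t0) {
        seg_t0 <<- c(seg_t0, t0); seg_t1 <<- c(seg_t1, t1)
        seg_p0 <<- c(seg_p0, p0); seg_p1 <<- c(seg_p1, p1)
        seg_f <<- c(seg_f, f)
      }
    }
    runs <- list(); steps <- list(); events <- list()
    run_id <- 0L
    while (t < duration) {
      # --- unbound: triangular sweep until attachment or end of record
      wait <- stats::rexp(1L, cfg$attach_rate)
      t_stop <- min(t + wait, duration)
      while (t < t_stop) {
        t_edge <- if (dir > 0L) (D - p) / v else p / v
        dt_seg <- min(t_edge, t_stop - t)
        p_new <- p + dir * v * dt_seg
        add_seg(t, t + dt_seg, p, p_new, dir * Fm)
        t <- t + dt_seg; p <- p_new
        if (dt_seg >= t_edge - 1e-15) dir <- -dir
      }
      if (t >= duration) break
      # --- attached: signed force label; motor walks toward +x, so a force
      # pushing +x is assistive (negative by convention)
      f_signed <- if (dir > 0L) -Fm else Fm
      rates <- stepping_rates(model, f_signed)
      st <- sim_run_events(model, f_signed, rates, t0 = t, pos0 = p,
                           t_max = duration, window = c(0, D),
                           trunc_dir = dir)
      run_id <- run_id + 1L
      ev_t <- st$time; ev_p <- st$position
      # constant-position dwell segments between events
      for (i in seq_len(nrow(st) - 1L)) {
        add_seg(ev_t[i], ev_t[i + 1L], ev_p[i], ev_p[i], dir * Fm)
      }
      if (isTRUE(attr(st, "censored")) && !isTRUE(attr(st, "truncated"))) {
        add_seg(ev_t[length(ev_t)], duration, ev_p[length(ev_p)],
                ev_p[length(ev_p)], dir * Fm)
      }
      is_step <- st$kind %in% c("step_fwd", "step_bwd")
      if (any(is_step)) {
        sizes <- diff(st$position)[is_step[-1L]]
        steps[[run_id]] <- data.frame(
          run_id = run_id, time = st$time[is_step], size = sizes)
      }
      runs[[run_id]] <- data.frame(
        run_id = run_id,
        t_start = ev_t[1L], t_end = max(ev_t),
        pos_start = ev_p[1L], pos_end = ev_p[length(ev_p)],
        force = f_signed,
        n_fwd = sum(st$kind == "step_fwd"),
        n_bwd = sum(st$kind == "step_bwd"),
        truncated = isTRUE(attr(st, "truncated")),
        censored = isTRUE(attr(st, "censored")) &&
          !isTRUE(attr(st, "truncated")))
      events[[run_id]] <- st
      t <- max(ev_t)
      p <- ev_p[length(ev_p)]
      if (isTRUE(attr(st, "truncated"))) dir <- -dir
    }
    truth <- list(
      runs = if (length(runs)) do.call(rbind, runs) else NULL,
      steps = if (length(steps)) do.call(rbind, steps) else NULL,
      events = events,
      segments = data.frame(t0 = seg_t0, t1 = seg_t1, p0 = seg_p0,
                            p1 = seg_p1, force = seg_f))
    rec <- list(position = NULL, force = NULL, dt = 1 / cfg$sample_rate,
                duration = duration, config = cfg, model = model,
                truth = truth)
    if (render) {
      n <- floor(duration * cfg$sample_rate)
      ts <- (seq_len(n) - 1L) / cfg$sample_rate
      idx <- findInterval(ts, seg_t0)
      idx[idx < 1L] <- 1L
      span <- seg_t1[idx] - seg_t0[idx]
      frac <- (ts - seg_t0[idx]) / span
      frac[!is.finite(frac)] <- 0
      pos <- seg_p0[idx] + frac * (seg_p1[idx] - seg_p0[idx])
      if (cfg$noise_sigma > 0) {
        pos <- pos + stats::rnorm(n, 0, cfg$noise_sigma)
      }
      rec$position <- pos
      rec$force <- seg_f[idx]
    }
    structure(rec, class = "position_record")
  })
}

#' @export
print.position_record <- function(x, ...) {
  nr <- if (is.null(x$truth$runs)) 0L else nrow(x$truth$runs)
  cat(sprintf("<position_record> %.3g s at %g Hz, |F| = %g pN, %d runs%s\n",
              x$duration, 1 / x$dt, x$config$force_magnitude, nr,
              if (is.null(x$position)) " (not rendered)" else ""))
  invisible(x)
}

#' Simulate an unloaded single-molecule motility trajectory
#'
#' One QD-labelled motor walking along a straight filament: steps of
#' \code{step_size} at exponential dwell times with rate
#' \code{velocity / step_size}; the number of steps is geometric so that
#' the total run length is (discretized) exponential with the requested
#' mean. Positions are sampled at \code{frame_interval} with isotropic
#' Gaussian localization noise.
#'
#' @param velocity mean unloaded velocity (nm/s).
#' @param run_length_mean mean total run length (nm).
#' @param frame_interval camera frame interval (s).
#' @param loc_noise per-axis localization noise (nm).
#' @param seed optional RNG seed.
#' @param step_size step size (nm, default 36).
#' @param angle filament direction (radians) in the image plane.
#' @param origin numeric length-2 start position (nm).
#' @return data frame (class \code{sm_trajectory}) with columns
#'   \code{frame}, \code{time}, \code{x}, \code{y} (nm), carrying
#'   attributes \code{true_run_length}, \code{true_duration},
#'   \code{n_steps}.
#' @export
simulate_motility_trajectory <- function(velocity, run_length_mean,
                                         frame_interval, loc_noise,
                                         seed = NULL, step_size = 36,
                                         angle = 0, origin = c(0, 0)) {
  stop_if_not_positive(velocity, "velocity")
  stop_if_not_positive(run_length_mean, "run_length_mean")
  stop_if_not_positive(frame_interval, "frame_interval")
  stopifnot(loc_noise >= 0)
  with_seed(seed, {
    step_rate <- velocity / step_size
    n_steps <- stats::rgeom(1L, step_size / (run_length_mean + step_size))
    dwells <- stats::rexp(n_steps + 1L, step_rate)
    step_times <- cumsum(dwells)[seq_len(n_steps)]
    duration <- sum(dwells)
    n_frames <- floor(duration / frame_interval) + 1L
    t_frames <- (seq_len(n_frames) - 1L) * frame_interval
    s <- step_size * findInterval(t_frames, step_times)
    x <- origin[1L] + cos(angle) * s
    y <- origin[2L] + sin(angle) * s
    if (loc_noise > 0) {
      x <- x + stats::rnorm(n_frames, 0, loc_noise)
      y <- y + stats::rnorm(n_frames, 0, loc_noise)
    }
    structure(data.frame(frame = seq_len(n_frames) - 1L, time = t_frames,
                         x = x, y = y),
              true_run_length = step_size * n_steps,
              true_duration = duration,
              n_steps = n_steps,
              class = c("sm_trajectory", "data.frame"))
  })
}

#' Draw run lengths from the edge-truncated exponential density
#'
#' Samples from the density of measured (edge-censored) run lengths under
#' an oscillation window of width \code{D},
#' \deqn{p(x) = e^{-x/L}\left(\frac1L + \frac1D - \frac{x}{DL}\right),
#'   \quad 0 \le x \le D,}
#' the product rule of an exponential true run length (mean \code{L}) and a
#' uniform attachment position. Uses rejection sampling from a truncated
#' exponential envelope (acceptance probability \code{1 - x/(D+L)}).
#'
#' @param L true mean run length (nm).
#' @param D oscillation window width (nm).
#' @param n number of draws.
#' @param seed optional RNG seed.
#' @return numeric vector of n run lengths in [0, D].
#' @seealso [truncated_pdf()], [expected_measured_runlength()]
#' @export
sample_truncated_run_lengths <- function(L, D, n, seed = NULL) {
  stop_if_not_positive(L, "L")
  stop_if_not_positive(D, "D")
  stopifnot(n >= 1L)
  with_seed(seed, {
    out <- numeric(0L)
    p_trunc <- -expm1(-D / L)   # 1 - exp(-D/L)
    while (length(out) < n) {
      m <- max(64L, ceiling(1.5 * (n - length(out))))
      x <- -L * log1p(-stats::runif(m) * p_trunc)  # truncated exponential
      keep <- stats::runif(m) < 1 - x / (D + L)
      out <- c(out, x[keep])
    }
    out[seq_len(n)]
  })
}

#' Simulated per-force sample tables for model-layer fitting
#'
#' Generators for the tabular inputs of the model layer: exponential run
#' lengths or run durations whose force dependence follows a Bell model,
#' per-force forward/backward step counts following an exponential
#' count-ratio model, and per-run velocities scattered around a
#' Michaelis-Menten ATP curve. These emulate the per-run observables of a
#' force-clamp or motility experiment without simulating full records.
#'
#' @param L0,dL zero-force mean run length (nm) and its distance parameter
#'   (nm).
#' @param k0,dk zero-force detachment rate (s^-1) and distance parameter
#'   (nm).
#' @param R0,dR zero-force forward/backward count ratio and distance
#'   parameter (nm).
#' @param forces signed forces (pN), one level per entry.
#' @param n_per runs per force level (recycled).
#' @param n_total total number of steps to distribute as evenly as possible
#'   across force levels.
#' @param vmax,Kapp Michaelis-Menten parameters (nm/s, uM).
#' @param atp ATP levels (uM).
#' @param cv multiplicative (lognormal) coefficient of variation of per-run
#'   velocities.
#' @param kBT thermal energy (pN nm).
#' @param seed optional RNG seed.
#' @return data frames: \code{(force, run_length)}, \code{(force, duration)},
#'   \code{(force, n_fwd, n_bwd)}, or \code{(atp, velocity)}.
#' @name sample_tables
NULL

#' @rdname sample_tables
#' @export
simulate_run_length_table <- function(L0, dL, forces, n_per, kBT = 4.114,
                                      seed = NULL) {
  stop_if_not_positive(L0, "L0")
  with_seed(seed, {
    n_per <- rep_len(n_per, length(forces))
    do.call(rbind, Map(function(f, n) {
      Lf <- L0 * exp(-abs(f) * dL / kBT)
      data.frame(force = f, run_length = stats::rexp(n, 1 / Lf))
    }, forces, n_per))
  })
}

#' @rdname sample_tables
#' @export
simulate_duration_table <- function(k0, dk, forces, n_per, kBT = 4.114,
                                    seed = NULL) {
  stop_if_not_positive(k0, "k0")
  with_seed(seed, {
    n_per <- rep_len(n_per, length(forces))
    do.call(rbind, Map(function(f, n) {
      kf <- k0 * exp(abs(f) * dk / kBT)
      data.frame(force = f, duration = stats::rexp(n, kf))
    }, forces, n_per))
  })
}

#' @rdname sample_tables
#' @export
simulate_step_count_table <- function(R0, dR, forces, n_total, kBT = 4.114,
                                      seed = NULL) {
  stop_if_not_positive(R0, "R0")
  stopifnot(n_total >= length(forces))
  with_seed(seed, {
    k <- length(forces)
    n_lev <- rep(n_total %/% k, k)
    extra <- n_total %% k
    if (extra > 0) n_lev[seq_len(extra)] <- n_lev[seq_len(extra)] + 1L
    do.call(rbind, Map(function(f, n) {
      R <- R0 * exp(-abs(f) * dR / kBT)
      nf <- stats::rbinom(1L, n, R / (1 + R))
      data.frame(force = f, n_fwd = nf, n_bwd = n - nf)
    }, forces, n_lev))
  })
}

#' @rdname sample_tables
#' @export
simulate_velocity_table <- function(vmax, Kapp, atp, n_total, cv = 0.15,
                                    seed = NULL) {
  stop_if_not_positive(vmax, "vmax")
  stop_if_not_positive(Kapp, "Kapp")
  with_seed(seed, {
    k <- length(atp)
    n_lev <- rep(n_total %/% k, k)
    extra <- n_total %% k
    if (extra > 0) n_lev[seq_len(extra)] <- n_lev[seq_len(extra)] + 1L
    sdlog <- sqrt(log1p(cv^2))
    do.call(rbind, Map(function(a, n) {
      v <- vmax * a / (Kapp + a)
      data.frame(atp = a,
                 velocity = v * stats::rlnorm(n, -sdlog^2 / 2, sdlog))
    }, atp, n_lev))
  })
}
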
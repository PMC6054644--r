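#' Kinetic model of a load-dependent processive motor
#'
#' Bundles the generative parameters of a two-branch Bell-type stepping
#' scheme: within one attachment, forward stepping, backward stepping and
#' detachment compete as memoryless (exponential) clocks whose rates depend
#' exponentially on the applied load,
#' \deqn{k(F) = k_0 \exp(|F| d / k_B T),}
#' with separate parameter sets for the assistive (\code{_minus}, force < 0)
#' and resistive (\code{_plus}, force > 0) branches. Defaults are the fitted
#' stepping and detachment parameters of a single myosin-5B HMM measured
#' under ultrafast force clamp at 100 uM ATP.
#'
#' @param k0f_plus,df_plus forward stepping rate at zero force (s^-1) and its
#'   distance parameter (nm) on the resistive branch.
#' @param k0b_plus,db_plus backward stepping analogues, resistive branch.
#' @param k0f_minus,df_minus forward stepping parameters, assistive branch.
#' @param k0b_minus,db_minus backward stepping parameters, assistive branch.
#' @param kd0_plus,dk_plus zero-force detachment rate (s^-1) and detachment
#'   distance parameter (nm), resistive branch.
#' @param kd0_minus,dk_minus detachment parameters, assistive branch.
#' @param step_fwd forward step size (nm); 36 nm matches the actin
#'   pseudo-repeat.
#' @param step_bwd backward step size magnitude (nm).
#' @param short_step_prob_scale steepness (per pN) of the optional
#'   "inchworm" short-step mixture. 0 (default) disables it; when positive,
#'   the probability of a short step (20 nm forward under resistive load,
#'   15 nm backward under assistive load) is a logistic function of
#'   \code{scale * (|F| - 1 pN)}.
#' @param kBT thermal energy in pN nm (default 4.114, T = 298 K).
#'
#' @return An object of class \code{motor_model} (a validated list).
#' @seealso [stepping_rates()], [simulate_stepping()]
#' @export
motor_model <- function(k0f_plus = 6.5, df_plus = 2.2,
                        k0b_plus = 10, db_plus = 2.0,
                        k0f_minus = 14.6, df_minus = 0.05,
                        k0b_minus = 54.1, db_minus = 2.4,
                        kd0_plus = 0.64, dk_plus = 4.2,
                        kd0_minus = 2.3, dk_minus = 1.9,
                        step_fwd = 36, step_bwd = 30,
                        short_step_prob_scale = 0,
                        kBT = 4.114) {
  m <- list(k0f_plus = k0f_plus, df_plus = df_plus,
            k0b_plus = k0b_plus, db_plus = db_plus,
            k0f_minus = k0f_minus, df_minus = df_minus,
            k0b_minus = k0b_minus, db_minus = db_minus,
            kd0_plus = kd0_plus, dk_plus = dk_plus,
            kd0_minus = kd0_minus, dk_minus = dk_minus,
            step_fwd = step_fwd, step_bwd = step_bwd,
            short_step_prob_scale = short_step_prob_scale,
            kBT = kBT)
  rates <- m[c("k0f_plus", "k0b_plus", "k0f_minus", "k0b_minus",
               "kd0_plus", "kd0_minus")]
  dists <- m[c("df_plus", "db_plus", "df_minus", "db_minus",
               "dk_plus", "dk_minus")]
  if (!all(vapply(m, function(x) is.numeric(x) && length(x) == 1L &&
                    is.finite(x), logical(1L)))) {
    stop("all motor_model parameters must be finite numeric scalars",
         call. = FALSE)
  }
  if (any(unlist(rates) <= 0)) stop("all rates must be > 0", call. = FALSE)
  if (any(unlist(dists) < 0)) {
    stop("distance parameters must be >= 0", call. = FALSE)
  }
  if (kBT <= 0) stop("kBT must be > 0", call. = FALSE)
  if (step_fwd <= 0 || step_fwd >= 90 || step_bwd <= 0 || step_bwd >= 90) {
    stop("step sizes must lie in (0, 90) nm", call. = FALSE)
  }
  if (short_step_prob_scale < 0) {
    stop("short_step_prob_scale must be >= 0", call. = FALSE)
  }
  structure(m, class = "motor_model")
}

#' @export
print.motor_model <- function(x, ...) {
  cat("<motor_model>\n")
  cat(sprintf("  forward : k0+ = %.3g s^-1 (d = %.3g nm) | k0- = %.3g s^-1 (d = %.3g nm)\n",
              x$k0f_plus, x$df_plus, x$k0f_minus, x$df_minus))
  cat(sprintf("  backward: k0+ = %.3g s^-1 (d = %.3g nm) | k0- = %.3g s^-1 (d = %.3g nm)\n",
              x$k0b_plus, x$db_plus, x$k0b_minus, x$db_minus))
  cat(sprintf("  detach  : k0+ = %.3g s^-1 (d = %.3g nm) | k0- = %.3g s^-1 (d = %.3g nm)\n",
              x$kd0_plus, x$dk_plus, x$kd0_minus, x$dk_minus))
  cat(sprintf("  steps   : +%g / -%g nm; kBT = %g pN nm\n",
              x$step_fwd, x$step_bwd, x$kBT))
  invisible(x)
}

#' Instantaneous stepping and detachment rates at a signed force
#'
#' Evaluates the three competing clocks of a \code{\link{motor_model}} at a
#' signed force (assistive < 0, resistive > 0). At exactly zero force the
#' mean of the two branch rates is used (relevant only to the simulator;
#' loaded data always carry a sign).
#'
#' @param model a [motor_model()].
#' @param force signed force in pN.
#' @return list with components \code{k_fwd}, \code{k_bwd}, \code{k_det}
#'   (s^-1).
#' @export
stepping_rates <- function(model, force) {
  stopifnot(inherits(model, "motor_model"),
            is.numeric(force), length(force) == 1L, is.finite(force))
  f <- abs(force)
  bell <- function(k0, d) k0 * exp(f * d / model$kBT)
  plus <- list(k_fwd = bell(model$k0f_plus, model$df_plus),
               k_bwd = bell(model$k0b_plus, model$db_plus),
               k_det = bell(model$kd0_plus, model$dk_plus))
  minus <- list(k_fwd = bell(model$k0f_minus, model$df_minus),
                k_bwd = bell(model$k0b_minus, model$db_minus),
                k_det = bell(model$kd0_minus, model$dk_minus))
  out <- if (force > 0) {
    plus
  } else if (force < 0) {
    minus
  } else {
    Map(function(a, b) (a + b) / 2, plus, minus)
  }
  if (!all(vapply(out, is.finite, logical(1L)))) {
    stop("non-finite rate at force ", force, " pN; check parameterization",
         call. = FALSE)
  }
  out
}

#' Configuration of an ultrafast force-clamp measurement
#'
#' Geometry and noise of the dumbbell assay: a constant-magnitude force is
#' clamped on the bead-actin-bead dumbbell and its sign alternated so that,
#' while no motor is attached, the dumbbell sweeps a triangular wave across
#' a user-set spatial window of width \code{oscillation_range} at
#' \code{drag_velocity}. Attachment stops the dumbbell and the record then
#' follows the motor's stepping staircase.
#'
#' @param force_magnitude net clamped force magnitude (pN).
#' @param oscillation_range window width D (nm) swept by the unbound
#'   dumbbell; assistive runs are censored at its edge.
#' @param sample_rate acquisition rate (Hz); the feedback and acquisition
#'   run at 200 kHz on the real instrument.
#' @param noise_sigma per-sample Gaussian position noise (nm). The default
#'   8 nm at 200 kHz corresponds to sub-nm noise after millisecond
#'   averaging.
#' @param drag_velocity dumbbell speed while unbound (nm/s), set by the
#'   force and the viscous drag.
#' @param attach_rate motor attachment rate while the dumbbell sweeps
#'   (s^-1); a nuisance parameter of the geometry, not of the motor.
#' @return object of class \code{clamp_config}.
#' @export
clamp_config <- function(force_magnitude = 1,
                         oscillation_range = 400,
                         sample_rate = 200000,
                         noise_sigma = 8,
                         drag_velocity = 2000,
                         attach_rate = 1) {
  stop_if_not_positive(force_magnitude, "force_magnitude")
  stop_if_not_positive(oscillation_range, "oscillation_range")
  stop_if_not_positive(sample_rate, "sample_rate")
  stop_if_not_positive(drag_velocity, "drag_velocity")
  stop_if_not_positive(attach_rate, "attach_rate")
  if (!is.numeric(noise_sigma) || noise_sigma < 0) {
    stop("noise_sigma must be >= 0", call. = FALSE)
  }
  structure(list(force_magnitude = force_magnitude,
                 oscillation_range = oscillation_range,
                 sample_rate = sample_rate,
                 noise_sigma = noise_sigma,
                 drag_velocity = drag_velocity,
                 attach_rate = attach_rate),
            class = "clamp_config")
}

#' @export
print.clamp_config <- function(x, ...) {
  cat("<clamp_config>\n")
  cat(sprintf("  |F| = %g pN, D = %g nm, fs = %g Hz\n",
              x$force_magnitude, x$oscillation_range, x$sample_rate))
  cat(sprintf("  noise = %g nm, drag velocity = %g nm/s, attach rate = %g s^-1\n",
              x$noise_sigma, x$drag_velocity, x$attach_rate))
  invisible(x)
}
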
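#' Bell-type exponential force-dependence fit
#'
#' Fits the single-exponential load dependence used throughout motor
#' mechanics,
#' \deqn{y(F) = A \exp\left(s \frac{|F| d}{k_B T}\right),}
#' with \code{s = -1} for decaying observables (run length, forward/backward
#' count ratio) and \code{s = +1} for growing ones (detachment and stepping
#' rates). The default is weighted nonlinear least squares on the natural
#' scale (weights \code{1/sem^2} when standard errors are supplied); a
#' log-linear fit with delta-method errors is available as a cross-check.
#'
#' @param force signed forces (pN); all points must lie on one branch.
#' @param y observable values (> 0) at each force.
#' @param sem optional standard errors of \code{y}, used as weights.
#' @param sign \code{"decay"} or \code{"growth"}: sign of the exponent.
#' @param branch \code{"resistive"} (F > 0) or \code{"assistive"} (F < 0);
#'   inferred from the force signs when omitted.
#' @param kBT thermal energy (pN nm).
#' @param method \code{"nls"} (default) or \code{"loglinear"}.
#' @return object of class \code{bell_fit}: list with \code{amplitude0},
#'   \code{distance} (nm), their standard errors \code{amplitude0_se},
#'   \code{distance_se}, plus \code{sign}, \code{branch}, \code{kBT},
#'   \code{method} and the underlying fit object.
#' @seealso [bell_predict()], [stall_force()]
#' @export
fit_bell <- function(force, y, sem = NULL,
                     sign = c("decay", "growth"),
                     branch = NULL, kBT = 4.114,
                     method = c("nls", "loglinear")) {
  sign <- match.arg(sign)
  method <- match.arg(method)
  stopifnot(length(force) == length(y))
  if (is.null(branch)) {
    branch <- if (all(force >= 0)) "resistive" else if (all(force <= 0)) {
      "assistive"
    } else {
      stop("forces span both branches; fit each branch separately",
           call. = FALSE)
    }
  }
  branch <- match.arg(branch, c("resistive", "assistive"))
  keep <- is.finite(force) & is.finite(y) & y > 0
  if (!is.null(sem)) keep <- keep & is.finite(sem) & sem > 0
  if (any(!keep)) {
    warning(sum(!keep), " non-positive or non-finite point(s) excluded ",
            "from Bell fit")
  }
  force <- abs(force[keep]); y <- y[keep]
  if (!is.null(sem)) sem <- sem[keep]
  if (length(unique(force)) < 3L) {
    stop("need at least 3 distinct force levels on one branch",
         call. = FALSE)
  }
  s <- if (sign == "decay") -1 else 1
  w <- if (is.null(sem)) rep(1, length(y)) else 1 / sem^2
  # log-linear start values (also the cross-check fit)
  lw <- if (is.null(sem)) rep(1, length(y)) else (y / sem)^2
  ll <- stats::lm(log(y) ~ force, weights = lw)
  slope0 <- unname(stats::coef(ll)[2L])
  start <- list(A = exp(unname(stats::coef(ll)[1L])),
                d = max(0, s * slope0 * kBT))
  if (method == "loglinear") {
    cf <- suppressWarnings(summary(ll))$coefficients  # exact-data fits
    A <- exp(cf[1L, 1L]); d <- s * cf[2L, 1L] * kBT
    out <- list(amplitude0 = A, amplitude0_se = A * cf[1L, 2L],
                distance = d, distance_se = cf[2L, 2L] * kBT,
                fit = ll)
  } else {
    dat <- data.frame(force = force, y = y)
    fit <- minpack.lm::nlsLM(
      y ~ A * exp(s * force * d / kBT), data = dat,
      start = start, weights = w,
      lower = c(A = .Machine$double.eps, d = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- suppressWarnings(summary(fit))$coefficients  # exact-data fits
    out <- list(amplitude0 = cf["A", 1L], amplitude0_se = cf["A", 2L],
                distance = cf["d", 1L], distance_se = cf["d", 2L],
                fit = fit)
  }
  structure(c(out, list(sign = sign, branch = branch, kBT = kBT,
                        method = method,
                        data = data.frame(force = force, y = y))),
            class = "bell_fit")
}

#' @export
print.bell_fit <- function(x, ...) {
  cat(sprintf("<bell_fit> %s branch, %s\n", x$branch, x$sign))
  cat(sprintf("  amplitude0 = %.4g +/- %.3g\n", x$amplitude0,
              x$amplitude0_se))
  cat(sprintf("  distance   = %.4g +/- %.3g nm (kBT = %g pN nm)\n",
              x$distance, x$distance_se, x$kBT))
  invisible(x)
}

#' Evaluate a Bell model at a signed force
#'
#' @param force signed force(s) in pN; the sign must match the branch of
#'   the fit (zero is always allowed and returns the amplitude).
#' @param fit a \code{bell_fit}, or a list with \code{amplitude0},
#'   \code{distance}, \code{sign}, \code{kBT}.
#' @return predicted value(s) \code{amplitude0 * exp(s |F| d / kBT)}.
#' @export
bell_predict <- function(force, fit) {
  stopifnot(!is.null(fit$amplitude0), !is.null(fit$distance))
  if (!is.null(fit$branch)) {
    bad <- if (fit$branch == "resistive") any(force < 0) else any(force > 0)
    if (bad) {
      stop("force sign does not match the ", fit$branch,
           " branch of the fit", call. = FALSE)
    }
  }
  s <- if (identical(fit$sign, "growth")) 1 else -1
  kBT <- if (is.null(fit$kBT)) 4.114 else fit$kBT
  fit$amplitude0 * exp(s * abs(force) * fit$distance / kBT)
}

#' Fit the exponential forward/backward step-count ratio model to counts
#'
#' Maximum-likelihood fit of
#' \eqn{R(F) = N_{fwd}/N_{bwd} = R_0 \exp(-|F| d / k_B T)} to per-force
#' forward/backward step counts. Since each step is a Bernoulli trial with
#' odds \eqn{R(F)}, the model is exactly a binomial logistic regression in
#' force, which uses the raw counts more efficiently than least squares on
#' the per-level ratios (backward steps are scarce far below stall). A
#' [fit_bell()] on the per-level ratios is available as a cross-check via
#' \code{method = "ratio_ls"}.
#'
#' @param force signed forces (pN), one row per level.
#' @param n_fwd,n_bwd forward/backward step counts per level.
#' @param kBT thermal energy (pN nm).
#' @param method \code{"binomial"} (maximum likelihood, default) or
#'   \code{"ratio_ls"} (weighted least squares on the ratios).
#' @return a \code{bell_fit} with \code{amplitude0} = R0 and
#'   \code{distance} = d (nm); delta-method standard errors for the
#'   binomial fit.
#' @seealso [stall_force()]
#' @export
fit_step_ratio <- function(force, n_fwd, n_bwd, kBT = 4.114,
                           method = c("binomial", "ratio_ls")) {
  method <- match.arg(method)
  stopifnot(length(force) == length(n_fwd),
            length(force) == length(n_bwd))
  if (any(force < 0) && any(force > 0)) {
    stop("forces span both branches; fit each branch separately",
         call. = FALSE)
  }
  branch <- if (all(force >= 0)) "resistive" else "assistive"
  if (method == "ratio_ls") {
    ok <- n_bwd > 0
    r <- n_fwd[ok] / n_bwd[ok]
    sem_r <- r * sqrt(1 / n_fwd[ok] + 1 / n_bwd[ok])
    return(fit_bell(force[ok], r, sem = sem_r, sign = "decay",
                    branch = branch, kBT = kBT))
  }
  f <- abs(force)
  g <- stats::glm(cbind(n_fwd, n_bwd) ~ f, family = stats::binomial())
  cf <- summary(g)$coefficients
  R0 <- exp(cf[1L, 1L])
  structure(list(amplitude0 = R0,
                 amplitude0_se = R0 * cf[1L, 2L],
                 distance = -cf[2L, 1L] * kBT,
                 distance_se = cf[2L, 2L] * kBT,
                 fit = g, sign = "decay", branch = branch, kBT = kBT,
                 method = "binomial",
                 data = data.frame(force = f, n_fwd = n_fwd,
                                   n_bwd = n_bwd)),
            class = "bell_fit")
}

#' Stall force from a forward/backward step-count ratio model
#'
#' The force at which the fitted exponential count-ratio model
#' \eqn{R(F) = R_0 \exp(-F d / k_B T)} equals one, i.e. where forward and
#' backward stepping balance:
#' \deqn{F^{*} = \frac{k_B T}{d} \ln R_0.}
#'
#' @param R0 zero-force forward/backward count ratio (> 1 for a
#'   plus-end-directed motor).
#' @param d distance parameter of the ratio model (nm, > 0).
#' @param kBT thermal energy (pN nm).
#' @return stall force in pN.
#' @export
stall_force <- function(R0, d, kBT = 4.114) {
  stop_if_not_positive(d, "d")
  stop_if_not_positive(kBT, "kBT")
  if (!is.numeric(R0) || R0 <= 1) {
    stop("R0 must exceed 1: no positive stall force exists otherwise",
         call. = FALSE)
  }
  kBT / d * log(R0)
}

#' Edge-truncated run-length distribution
#'
#' Survival function and density of the run length measured under a finite
#' oscillation window of width \code{D}. The true run length is exponential
#' with mean \code{L} (survival \eqn{e^{-x/L}}) and the attachment position
#' is uniform over the window (survival \eqn{1 - x/D}); their product gives
#' \deqn{S(x) = e^{-x/L}(1 - x/D), \qquad
#'       p(x) = e^{-x/L}\left(\frac1L + \frac1D - \frac{x}{DL}\right)}
#' on \eqn{[0, D]} and 0 beyond.
#'
#' @param x run length(s), nm; must be >= 0.
#' @param L true mean run length (nm).
#' @param D oscillation window width (nm).
#' @return survival probabilities / density values at \code{x}.
#' @export
truncated_survival <- function(x, L, D) {
  stop_if_not_positive(L, "L")
  stop_if_not_positive(D, "D")
  if (any(x < 0)) stop("x must be >= 0", call. = FALSE)
  ifelse(x > D, 0, exp(-x / L) * (1 - x / D))
}

#' @rdname truncated_survival
#' @export
truncated_pdf <- function(x, L, D) {
  stop_if_not_positive(L, "L")
  stop_if_not_positive(D, "D")
  if (any(x < 0)) stop("x must be >= 0", call. = FALSE)
  ifelse(x > D, 0, exp(-x / L) * (1 / L + 1 / D - x / (D * L)))
}

#' Expected measured run length under edge truncation
#'
#' Closed-form mean of the edge-truncated run-length density:
#' \deqn{\langle L_m \rangle = \frac1D\left[L^2\left(e^{-D/L} - 1\right)
#'   + L D\right].}
#' Limits: \eqn{L_m \to L} as \eqn{D \to \infty} (no truncation) and
#' \eqn{L_m \to D/2} as \eqn{L \to \infty} (every run censored at a uniform
#' attachment point).
#'
#' @param L true mean run length (nm).
#' @param D oscillation window width (nm).
#' @return expected measured mean run length (nm).
#' @export
expected_measured_runlength <- function(L, D) {
  stop_if_not_positive(D, "D")
  if (any(L <= 0)) stop("L must be > 0", call. = FALSE)
  # expm1 keeps precision in the large-D/L regime
  (L^2 * expm1(-D / L) + L * D) / D
}

# d<Lm>/dL, used for delta-method error propagation and as a monotonicity
# certificate for the numerical inversion.
dLm_dL <- function(L, D) {
  (2 * L * expm1(-D / L) + D * exp(-D / L) + D) / D
}

#' Correct an edge-truncated mean run length
#'
#' Numerically inverts [expected_measured_runlength()] to recover the true
#' mean run length \code{L} from the measured mean \code{Lm} under a window
#' of width \code{D}. The forward map is strictly increasing in \code{L}
#' with supremum \code{D/2}, so a unique solution exists iff
#' \code{0 < Lm < D/2}.
#'
#' @param Lm measured mean run length (nm).
#' @param D oscillation window width (nm).
#' @param sem optional standard error of \code{Lm}; when given, the error
#'   is propagated by the delta method through the inverse map.
#' @param tol absolute root tolerance in nm.
#' @return corrected mean run length (nm); when \code{sem} is supplied, the
#'   standard error is attached as attribute \code{"se"}.
#' @export
correct_run_length <- function(Lm, D, sem = NULL, tol = 1e-3) {
  stop_if_not_positive(Lm, "Lm")
  stop_if_not_positive(D, "D")
  if (Lm >= D / 2) {
    stop(sprintf(paste0("no finite solution: measured mean (%.4g nm) ",
                        "reaches the geometric ceiling D/2 = %.4g nm"),
                 Lm, D / 2), call. = FALSE)
  }
  f <- function(L) expected_measured_runlength(L, D) - Lm
  hi <- max(2 * Lm, 1)
  while (f(hi) < 0) hi <- 2 * hi
  L <- stats::uniroot(f, lower = Lm * (1 - 1e-12), upper = hi,
                      tol = tol)$root
  if (!is.null(sem)) {
    attr(L, "se") <- sem / dLm_dL(L, D)
  }
  L
}

#' Michaelis-Menten fit of velocity or ATPase activity versus substrate
#'
#' Least-squares fit of \deqn{v([S]) = v_{max} [S] / (K_{app} + [S])}
#' to per-run velocities or ensemble ATPase rates.
#'
#' @param conc substrate concentrations (uM); at least 3 distinct levels.
#' @param v observed velocities (nm/s) or turnover rates (s^-1).
#' @param weights optional least-squares weights.
#' @return object of class \code{mm_fit}: \code{vmax}, \code{Kapp} with
#'   standard errors and the underlying \code{nls} fit.
#' @export
fit_michaelis_menten <- function(conc, v, weights = NULL) {
  stopifnot(length(conc) == length(v))
  if (length(unique(conc)) < 3L) {
    stop("need at least 3 distinct substrate levels", call. = FALSE)
  }
  dat <- data.frame(conc = conc, v = v)
  start <- list(vmax = max(v), Kapp = max(stats::median(conc), 1e-6))
  w <- if (is.null(weights)) rep(1, length(v)) else weights
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ vmax * conc / (Kapp + conc), data = dat,
                      start = start, weights = w,
                      lower = c(vmax = .Machine$double.eps,
                                Kapp = .Machine$double.eps),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop("Michaelis-Menten fit did not converge: ", conditionMessage(e),
           call. = FALSE)
    })
  cf <- suppressWarnings(summary(fit))$coefficients  # exact-data fits
  structure(list(vmax = cf["vmax", 1L], vmax_se = cf["vmax", 2L],
                 Kapp = cf["Kapp", 1L], Kapp_se = cf["Kapp", 2L],
                 fit = fit),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("<mm_fit>\n")
  cat(sprintf("  vmax = %.4g +/- %.3g\n", x$vmax, x$vmax_se))
  cat(sprintf("  Kapp = %.4g +/- %.3g uM\n", x$Kapp, x$Kapp_se))
  invisible(x)
}
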
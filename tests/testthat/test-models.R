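test_that("bell_predict evaluates the exponential load model", {
  fit <- list(amplitude0 = 890, distance = 6.3, sign = "decay",
              branch = "resistive", kBT = 4.114)
  expect_equal(bell_predict(0, fit), 890)
  expect_equal(bell_predict(2, fit), 890 * exp(-2 * 6.3 / 4.114))
  expect_equal(bell_predict(2, fit), 41.6, tolerance = 0.01)
  # halving the distance doubles the force scale
  fit2 <- fit; fit2$distance <- fit$distance / 2
  expect_equal(bell_predict(2, fit), bell_predict(4, fit2))
  expect_error(bell_predict(-1, fit), "branch")
})

test_that("fit_bell recovers exact exponential data to machine precision", {
  f <- c(0.5, 1, 1.5, 2, 2.5, 3)
  y <- 890 * exp(-f * 6.3 / 4.114)
  bf <- fit_bell(f, y, sign = "decay")
  expect_equal(bf$amplitude0, 890, tolerance = 1e-7)
  expect_equal(bf$distance, 6.3, tolerance = 1e-7)
  kg <- fit_bell(f, 0.64 * exp(f * 4.2 / 4.114), sign = "growth")
  expect_equal(kg$amplitude0, 0.64, tolerance = 1e-7)
  expect_equal(kg$distance, 4.2, tolerance = 1e-7)
  # log-linear cross-check agrees on exact data
  bl <- fit_bell(f, y, sign = "decay", method = "loglinear")
  expect_equal(bl$amplitude0, 890, tolerance = 1e-9)
  expect_equal(bl$distance, 6.3, tolerance = 1e-9)
})

test_that("fit_bell is scale-equivariant and handles degenerate slopes", {
  f <- c(0.5, 1, 1.5, 2, 2.5, 3)
  set.seed(1)
  y <- 500 * exp(-f * 3 / 4.114) * exp(rnorm(6, 0, 0.05))
  b1 <- fit_bell(f, y, sign = "decay")
  b2 <- fit_bell(f, 10 * y, sign = "decay")
  expect_equal(b2$amplitude0, 10 * b1$amplitude0, tolerance = 1e-6)
  expect_equal(b2$distance, b1$distance, tolerance = 1e-6)
  flat <- fit_bell(f, rep(100, 6) * exp(rnorm(6, 0, 1e-4)), sign = "decay")
  expect_lt(flat$distance, 0.01)
  expect_equal(flat$amplitude0, 100, tolerance = 0.01)
  expect_error(fit_bell(c(-1, 1, 2), c(1, 2, 3)), "both branches")
  expect_error(fit_bell(c(1, 2), c(1, 2)), "3 distinct")
  expect_warning(fit_bell(f, c(-1, y[-1]), sign = "decay"), "excluded")
})

test_that("stall force is the log ratio over the distance parameter", {
  expect_equal(stall_force(exp(1), 4.114, kBT = 4.114), 1)
  expect_equal(stall_force(54, 8.2), 2.0, tolerance = 0.01)
  expect_equal(stall_force(54, 16.4), stall_force(54, 8.2) / 2)
  expect_error(stall_force(0.9, 8), "R0")
  expect_error(stall_force(54, 0), "d")
})

test_that("truncated run-length distribution is a proper density", {
  for (L in c(50, 148, 500)) {
    for (D in c(200, 400)) {
      expect_equal(truncated_survival(0, L, D), 1)
      expect_equal(truncated_survival(D, L, D), 0)
      expect_equal(
        integrate(truncated_pdf, 0, D, L = L, D = D,
                  rel.tol = 1e-10)$value, 1, tolerance = 1e-8)
    }
  }
  # pdf is the negative derivative of the survival
  L <- 148; D <- 400; h <- 1e-5
  x <- seq(1, D - 1, length.out = 50)
  num <- -(truncated_survival(x + h, L, D) -
             truncated_survival(x - h, L, D)) / (2 * h)
  expect_equal(truncated_pdf(x, L, D), num, tolerance = 1e-6)
  expect_error(truncated_pdf(-1, L, D), "x must")
})

test_that("expected measured run length has the correct limits and monotonicity", {
  expect_equal(expected_measured_runlength(148, 1e9), 148,
               tolerance = 1e-6)
  expect_equal(expected_measured_runlength(1e9, 400), 200,
               tolerance = 1e-6)
  # strictly increasing in L and in D
  Ls <- seq(10, 2000, length.out = 100)
  expect_true(all(diff(expected_measured_runlength(Ls, 400)) > 0))
  Ds <- seq(50, 5000, length.out = 100)
  v <- vapply(Ds, function(D) expected_measured_runlength(148, D),
              numeric(1L))
  expect_true(all(diff(v) > 0))
})

test_that("run-length correction inverts the truncation map", {
  for (L in c(50, 148, 500)) {
    for (D in c(200, 400)) {
      Lm <- expected_measured_runlength(L, D)
      expect_equal(correct_run_length(Lm, D), L, tolerance = 1e-3)
    }
  }
  # short runs are barely censored
  expect_equal(correct_run_length(0.5, 400), 0.5, tolerance = 0.01)
  expect_error(correct_run_length(210, 400), "geometric ceiling")
  # delta-method error grows with the truncation severity
  se1 <- attr(correct_run_length(50, 400, sem = 5), "se")
  se2 <- attr(correct_run_length(190, 400, sem = 5), "se")
  expect_gt(se1, 5 - 1e-9)
  expect_gt(se2, se1)
})

test_that("step-ratio fit recovers the count-ratio model from raw counts", {
  forces <- seq(0.4, 1.9, length.out = 6)
  # large counts: the MLE should sit close to the generating model
  tab <- simulate_step_count_table(R0 = 54, dR = 8.2, forces = forces,
                                   n_total = 2e5, seed = 77)
  rf <- fit_step_ratio(tab$force, tab$n_fwd, tab$n_bwd)
  expect_lt(abs(rf$amplitude0 - 54) / 54, 0.05)
  expect_lt(abs(rf$distance - 8.2) / 8.2, 0.05)
  # least-squares cross-check route agrees with fit_bell on the ratios
  rl <- fit_step_ratio(tab$force, tab$n_fwd, tab$n_bwd,
                       method = "ratio_ls")
  bb <- fit_bell(tab$force, tab$n_fwd / tab$n_bwd,
                 sem = (tab$n_fwd / tab$n_bwd) *
                   sqrt(1 / tab$n_fwd + 1 / tab$n_bwd),
                 sign = "decay")
  expect_equal(rl$amplitude0, bb$amplitude0)
  expect_equal(rl$distance, bb$distance)
  # stall force from the fitted ratio model approaches the generating one
  expect_lt(abs(stall_force(rf$amplitude0, rf$distance) -
                  stall_force(54, 8.2)), 0.1)
})

test_that("Michaelis-Menten fit recovers exact and noisy kinetics", {
  atp <- c(0.3, 1, 5, 10, 100, 1000)
  v <- mm_velocity(atp)
  mf <- fit_michaelis_menten(atp, v)
  expect_equal(mf$vmax, 691, tolerance = 1e-6)
  expect_equal(mf$Kapp, 22, tolerance = 1e-6)
  expect_error(fit_michaelis_menten(c(1, 1, 10, 10), c(1, 1, 2, 2)),
               "3 distinct")
  tab <- simulate_velocity_table(691, 22, atp, n_total = 127, cv = 0.15,
                                 seed = 31)
  mf2 <- fit_michaelis_menten(tab$atp, tab$velocity)
  expect_lt(abs(mf2$vmax - 691), 2 * 25)
  expect_lt(abs(mf2$Kapp - 22), 2 * 2 + 2)
})

test_that("Michaelis-Menten velocity estimator is nearly unbiased", {
  atp <- c(0.3, 1, 5, 10, 100, 1000)
  est <- vapply(1:40, function(s) {
    tab <- simulate_velocity_table(691, 22, atp, n_total = 127,
                                   cv = 0.15, seed = 5000 + s)
    fit_michaelis_menten(tab$atp, tab$velocity)$vmax
  }, numeric(1L))
  # bias below ~1% of vmax (estimator noise allowance at 40 replicates)
  expect_lt(abs(mean(est) - 691),
            0.01 * 691 + 2 * sd(est) / sqrt(length(est)))
})
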
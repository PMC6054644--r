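test_that("model and config constructors validate their invariants", {
  expect_s3_class(motor_model(), "motor_model")
  expect_error(motor_model(k0f_plus = -1), "rates")
  expect_error(motor_model(df_plus = -0.1), "distance")
  expect_error(motor_model(step_fwd = 95), "step sizes")
  expect_error(motor_model(kBT = 0), "kBT")
  expect_error(clamp_config(noise_sigma = -1), "noise_sigma")
  expect_error(clamp_config(oscillation_range = -5), "oscillation_range")
})

test_that("single-clock limit: velocity approaches step size times rate", {
  m <- motor_model(k0f_plus = 10, k0b_plus = 1e-9, kd0_plus = 1e-9,
                   df_plus = 0, db_plus = 0, dk_plus = 0)
  st <- simulate_stepping(m, force = 1, max_duration = 400, seed = 1)
  v <- (st$position[nrow(st)] - st$position[1L]) / 400
  # N ~ Poisson(4000) steps: 3 sigma of the mean velocity is ~17 nm/s
  expect_lt(abs(v - 360), 18)
})

test_that("net displacement vanishes where forward and backward rates balance", {
  # resistive-branch stepping parameters; solve
  # k0f exp(F df / kBT) = k0b exp(F db / kBT) for F
  kBT <- 4.114
  Fbal <- kBT * log(10 / 6.5) / (2.2 - 2.0)
  m <- motor_model(k0f_plus = 6.5, df_plus = 2.2, k0b_plus = 10,
                   db_plus = 2.0, kd0_plus = 1e-9, dk_plus = 0,
                   step_bwd = 36)  # equal step sizes isolate the rate balance
  r <- stepping_rates(m, Fbal)
  expect_equal(r$k_fwd, r$k_bwd, tolerance = 1e-12)
  disp <- vapply(1:300, function(s) {
    st <- simulate_stepping(m, Fbal, max_duration = 0.2, seed = 1000 + s)
    st$position[nrow(st)] - st$position[1L]
  }, numeric(1L))
  expect_lt(abs(mean(disp)), 3 * sd(disp) / sqrt(length(disp)))
})

test_that("forward/backward step counts follow the rate ratio", {
  m <- gentle_model()
  f <- 1.5
  r <- stepping_rates(m, f)
  n_f <- 0L; n_b <- 0L
  for (s in 1:400) {
    st <- simulate_stepping(m, f, max_duration = 2, seed = 2000 + s)
    n_f <- n_f + sum(st$kind == "step_fwd")
    n_b <- n_b + sum(st$kind == "step_bwd")
  }
  p_hat <- n_f / (n_f + n_b)
  p_exp <- r$k_fwd / (r$k_fwd + r$k_bwd)
  se <- sqrt(p_exp * (1 - p_exp) / (n_f + n_b))
  expect_lt(abs(p_hat - p_exp), 3.5 * se)
})

test_that("run duration and run length converge to their kinetic expectations", {
  m <- gentle_model()
  f <- 1
  r <- stepping_rates(m, f)
  cfg <- clamp_config(force_magnitude = f, oscillation_range = 1e5,
                      sample_rate = 1000, noise_sigma = 0,
                      drag_velocity = 5000, attach_rate = 20)
  rec <- simulate_clamp_record(m, cfg, duration = 400, seed = 3,
                               render = FALSE)
  runs <- rec$truth$runs
  runs <- runs[!runs$censored & !runs$truncated, ]
  expect_gt(nrow(runs), 200)
  tau <- runs$t_end - runs$t_start
  len <- runs$pos_end - runs$pos_start
  expect_lt(abs(mean(tau) - 1 / r$k_det), 3 * sd(tau) / sqrt(length(tau)))
  len_exp <- (m$step_fwd * r$k_fwd - m$step_bwd * r$k_bwd) / r$k_det
  expect_lt(abs(mean(len) - len_exp), 3 * sd(len) / sqrt(length(len)))
})

test_that("stochastic operations are reproducible bit-for-bit", {
  m <- gentle_model()
  expect_identical(simulate_stepping(m, 1, 5, seed = 7),
                   simulate_stepping(m, 1, 5, seed = 7))
  cfg <- clamp_config(sample_rate = 10000)
  r1 <- simulate_clamp_record(m, cfg, duration = 2, seed = 7)
  r2 <- simulate_clamp_record(m, cfg, duration = 2, seed = 7)
  expect_identical(r1$position, r2$position)
  expect_identical(r1$truth$runs, r2$truth$runs)
  expect_identical(
    simulate_motility_trajectory(300, 780, 0.1, 4, seed = 7),
    simulate_motility_trajectory(300, 780, 0.1, 4, seed = 7))
  expect_identical(sample_truncated_run_lengths(150, 400, 100, seed = 7),
                   sample_truncated_run_lengths(150, 400, 100, seed = 7))
})

test_that("motor-free noiseless record is a pure triangular wave", {
  cfg <- clamp_config(force_magnitude = 1, oscillation_range = 400,
                      sample_rate = 20000, noise_sigma = 0,
                      drag_velocity = 2000, attach_rate = 1e-12)
  rec <- simulate_clamp_record(gentle_model(), cfg, duration = 1, seed = 1)
  expect_true(all(rec$position >= 0 & rec$position <= 400))
  # per-sample speed is exactly the drag velocity except at the turnarounds
  spd <- abs(diff(rec$position)) / rec$dt
  expect_lt(mean(abs(spd - 2000) > 1), 0.01)
  # period 2 D / v = 0.4 s: position autocorrelates with itself one period on
  n_per <- round(0.4 / rec$dt)
  expect_lt(max(abs(rec$position[1:(length(rec$position) - n_per)] -
                      rec$position[(n_per + 1):length(rec$position)])), 1e-6)
})

test_that("oscillation window below the step size is rejected", {
  cfg <- clamp_config(oscillation_range = 30)
  expect_error(simulate_clamp_record(gentle_model(), cfg), "oscillation")
})

test_that("assistive runs much longer than the window truncate to mean D/2", {
  # assistive branch near-immortal and fast (every assistive run hits the
  # window edge); resistive branch detaches quickly so it does not
  # monopolize the record
  m <- motor_model(k0f_plus = 200, k0b_plus = 1e-6, kd0_plus = 50,
                   k0f_minus = 200, k0b_minus = 1e-6, kd0_minus = 1e-4,
                   df_minus = 0, db_minus = 0, dk_minus = 0)
  D <- 400
  # slow attachment relative to the sweep, so the attachment position is
  # close to uniform over the window (the regime behind the correction)
  cfg <- clamp_config(force_magnitude = 1, oscillation_range = D,
                      sample_rate = 1000, noise_sigma = 0,
                      drag_velocity = 5000, attach_rate = 1)
  rec <- simulate_clamp_record(m, cfg, duration = 1500, seed = 5,
                               render = FALSE)
  runs <- rec$truth$runs
  assist <- runs[runs$force < 0, ]
  expect_gt(mean(assist$truncated), 0.99)
  len <- assist$pos_end - assist$pos_start
  # uniform attachment point: measured length -> U(0, D), mean D/2 (up to
  # the 36-nm step quantization)
  expect_lt(abs(mean(len) - D / 2), 3 * sd(len) / sqrt(length(len)) + 18)
})

test_that("resistive run lengths are not limited by the oscillation window", {
  m <- gentle_model()
  cfg <- clamp_config(force_magnitude = 1, oscillation_range = 2000,
                      sample_rate = 1000, noise_sigma = 0,
                      drag_velocity = 5000, attach_rate = 20)
  rec <- simulate_clamp_record(m, cfg, duration = 500, seed = 6,
                               render = FALSE)
  res <- rec$truth$runs[rec$truth$runs$force > 0, ]
  res <- res[!res$censored, ]
  expect_gt(nrow(res), 100)
  expect_equal(sum(res$truncated), 0L)
  r <- stepping_rates(m, 1)
  len <- res$pos_end - res$pos_start
  len_exp <- (m$step_fwd * r$k_fwd - m$step_bwd * r$k_bwd) / r$k_det
  expect_lt(abs(mean(len) - len_exp), 3.5 * sd(len) / sqrt(length(len)))
})

test_that("truncated run-length sampler matches its density", {
  L <- 150; D <- 400
  x <- sample_truncated_run_lengths(L, D, 2e4, seed = 9)
  expect_true(all(x >= 0 & x <= D))
  expect_lt(abs(mean(x) - expected_measured_runlength(L, D)),
            3 * sd(x) / sqrt(length(x)))
  # no-truncation limit
  y <- sample_truncated_run_lengths(50, 1e5, 2e4, seed = 10)
  expect_lt(abs(mean(y) - 50), 3 * sd(y) / sqrt(length(y)))
})

test_that("motility trajectories carry the requested kinematics", {
  # noiseless single step: plateau difference is exactly the step size
  tr <- simulate_motility_trajectory(36, 36, 0.1, 0, seed = 21)
  s <- unique(round(tr$x, 9))
  expect_true(all(diff(s) == 36))
  # mean frame-to-frame displacement = velocity * frame interval
  d <- unlist(lapply(1:150, function(s) {
    tr <- simulate_motility_trajectory(691, 5000, 0.1, 0, seed = 400 + s)
    if (nrow(tr) > 1) diff(tr$x)
  }))
  expect_lt(abs(mean(d) - 69.1), 3 * sd(d) / sqrt(length(d)))
  # ensemble mean run length within 2 s.e. of the generating mean
  rl <- vapply(1:200, function(s) {
    attr(simulate_motility_trajectory(500, 780, 0.1, 4, seed = 600 + s),
         "true_run_length")
  }, numeric(1L))
  expect_lt(abs(mean(rl) - 780), 2 * sd(rl) / sqrt(length(rl)))
})

test_that("image stacks render integrated PSFs with retained ground truth", {
  # zero photon rate: pure background
  tr <- list(data.frame(frame = 1, x_nm = 15 * 91, y_nm = 15 * 91))
  st0 <- simulate_image_stack(tr, dims = c(16, 16), photon_rate = 0,
                              background = 7, seed = 1)
  expect_true(all(st0$frames >= 0))
  expect_lt(abs(mean(st0$frames) - 7), 0.5)
  # two well-separated spots are both detected
  tr2 <- list(data.frame(frame = 1, x_nm = 8 * 91, y_nm = 10 * 91),
              data.frame(frame = 1, x_nm = 18 * 91, y_nm = 10 * 91))
  st2 <- simulate_image_stack(tr2, dims = c(24, 24), photon_rate = 3000,
                              background = 10, seed = 2)
  expect_equal(nrow(st2$ground_truth), 2L)
  cand <- detect_spots(st2$frames[1, , ], psf_sigma_px = 130 / 91)
  expect_equal(nrow(cand), 2L)
  # out-of-field spots are dropped with a warning
  tr3 <- list(data.frame(frame = 1, x_nm = -500, y_nm = 10 * 91))
  expect_warning(simulate_image_stack(tr3, dims = c(16, 16), seed = 3),
                 "outside the field")
})
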
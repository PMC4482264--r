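calib01 <- function(window = c(0, 10)) calibration_model(0, 1, window)

test_that("log-domain transform evaluates ln((x - P)/S) and guards it", {
  expect_equal(to_log_domain(exp(2), calib01()), 2)
  expect_equal(to_log_domain(5 + 3 * exp(1),
                             calibration_model(5, 3, c(0, 1))), 1)
  expect_error(to_log_domain(1.0, calibration_model(1, 2, c(0, 1))),
               "plateau")
  # table form names the offending sensor and time
  tbl <- mk_table(A = c(2, 0.5), time = c(0, 7))
  expect_error(to_log_domain(tbl, calibration_model(1, 2, c(0, 10))),
               "sensor 'A', time 7")
  # opt-in clipping replaces the hard error
  z <- to_log_domain(tbl, calibration_model(1, 2, c(0, 10)),
                     clip_epsilon = 1e-9)
  expect_equal(z$A[2], log(1e-9))
})

test_that("correction factors are window means and their plate mean", {
  tbl <- mk_table(A = exp(c(2, 2)), B = exp(c(4, 4)), time = c(0, 1))
  f <- compute_factors(tbl, calib01(c(0, 1)))
  expect_equal(f$m_s, c(2, 4))          # hand means
  expect_equal(attr(f, "m_p"), 3)
  expect_equal(f$factor, c(3 / 2, 3 / 4))
  expect_equal(mean(f$m_s), attr(f, "m_p"))  # invariant
  # identical sensors and single sensors get factor 1
  same <- mk_table(A = exp(c(2, 2)), B = exp(c(2, 2)), time = c(0, 1))
  expect_equal(compute_factors(same, calib01(c(0, 1)))$factor, c(1, 1))
  single <- mk_table(A = exp(c(2, 3)), time = c(0, 1))
  expect_equal(compute_factors(single, calib01(c(0, 1)))$factor, 1)
  # a window covering < 2 rows is rejected
  expect_error(compute_factors(tbl, calib01(c(0.2, 0.8))), "window")
})

test_that("recalibration maps both sensors of the worked example to e^3", {
  tbl <- mk_table(A = exp(c(2, 2)), B = exp(c(4, 4)), time = c(0, 1))
  out <- recalibrate(tbl, calib01(c(0, 1)))
  expect_equal(out$A, exp(c(3, 3)))
  expect_equal(out$B, exp(c(3, 3)))
  # all factors 1 => identity
  same <- mk_table(A = exp(c(2, 2.5)), B = exp(c(2, 3)), time = c(0, 1))
  f <- compute_factors(same, calib01(c(0, 1)))
  f$factor[] <- 1
  expect_equal(recalibrate(same, calib01(c(0, 1)), f), same,
               ignore_attr = TRUE)
})

test_that("recalibration collapses between-sensor spread of a gain-only plate", {
  cfg <- sim_config(noise_sd = 0, seed = 5)
  plate <- simulate_empty_plate(cfg)
  calib <- calibration_model(cfg$plateau, cfg$span, window = c(0, 9))
  rec <- recalibrate(plate, calib)
  pre_sd <- apply(as.matrix(plate[-1]), 1, sd)
  post_sd <- apply(as.matrix(rec[-1]), 1, sd)
  expect_lt(max(post_sd), 1e-9 * max(pre_sd))
})

test_that("target normalization sets every window mean exactly to target", {
  tbl <- mk_table(A = c(90, 90, 95), B = c(92, 92, 100), time = 0:2)
  out <- normalize_to_target(tbl, calib01(c(0, 1)), 91.3)
  expect_identical(mean(out$A[1:2]), 91.3)
  expect_identical(mean(out$B[1:2]), 91.3)
  # target equal to the current mean leaves that sensor untouched
  out2 <- normalize_to_target(tbl, calib01(c(0, 1)), 90)
  expect_equal(out2$A, tbl$A)
})

test_that("two-step correction restores a noiseless plate to truth", {
  cfg <- sim_config(noise_sd = 0, seed = 2)
  plate <- simulate_empty_plate(cfg)  # 5 oxygen levels, 10 points each
  # calibrate on the 48.1 segment, check recovery there
  calib <- calibration_model(cfg$plateau, cfg$span, window = c(20, 29))
  out <- correct_sensors(plate, calib, target = 48.1)
  expect_lt(max(abs(as.matrix(out[21:30, -1]) - 48.1)), 1e-6)
})

test_that("correction is idempotent", {
  cfg <- sim_config(noise_sd = 0, seed = 6)
  plate <- simulate_empty_plate(cfg)
  calib <- calibration_model(cfg$plateau, cfg$span, window = c(0, 9))
  once <- recalibrate(plate, calib)
  f2 <- compute_factors(once, calib)
  expect_lt(max(abs(f2$factor - 1)), 1e-9)
  twice <- recalibrate(once, calib, f2)
  expect_equal(as.matrix(twice[-1]), as.matrix(once[-1]), tolerance = 1e-9)
})

test_that("logarithmic correction beats naive multiply/divide correction", {
  # gain-miscalibrated sensors at several constant levels: after logarithmic
  # correction the between-sensor SD at every level must be <= the SD after
  # scaling each sensor to the target at the calibration level only
  cfg <- sim_config(noise_sd = 0, seed = 9, gain_delta = 0.05)
  levels <- c(91.3, 72.1, 48.1, 24.0, 4.8)
  plate <- simulate_empty_plate(cfg, levels = levels)
  calib <- calibration_model(cfg$plateau, cfg$span, window = c(0, 9))
  log_corr <- correct_sensors(plate, calib, target = 91.3)
  naive <- plate
  for (nm in measure_names(plate))
    naive[[nm]] <- plate[[nm]] * 91.3 / mean(plate[[nm]][1:10])
  for (lev in seq_along(levels)) {
    rows <- (lev - 1) * 10 + 1:10
    sd_log <- mean(apply(as.matrix(log_corr[rows, -1]), 1, sd))
    sd_naive <- mean(apply(as.matrix(naive[rows, -1]), 1, sd))
    expect_lte(sd_log, sd_naive)
  }
})

test_that("calibration curve estimation recovers exact exponential data", {
  y <- c(0, 20, 40, 70, 100)
  x <- 2 + 5 * exp(0.03 * y)
  fit <- estimate_calibration(data.frame(true_value = y, reading = x))
  expect_equal(fit$plateau, 2, tolerance = 1e-6)
  expect_equal(fit$span, 5, tolerance = 1e-6)
  expect_equal(fit$alpha, 0.03, tolerance = 1e-6)
  expect_error(estimate_calibration(
    data.frame(true_value = c(0, 10), reading = c(7, 9))), "3 distinct")
  expect_warning(estimate_calibration(
    data.frame(true_value = y, reading = 1 + 0.5 * y)), "linear")
})
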
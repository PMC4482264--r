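test_that("log-logistic evaluation satisfies the model identities", {
  expect_equal(loglogistic(50, b = 1, c = 0, d = 100, e = 50), 50)
  expect_equal(loglogistic(10, b = 2, c = 20, d = 90, e = 10), 55)
  expect_equal(loglogistic(0, b = 1, c = 0, d = 100, e = 50), 100)
  expect_equal(loglogistic(0, b = -1, c = 5, d = 100, e = 50), 5)
  expect_equal(loglogistic(1e12, b = 1, c = 3, d = 100, e = 50), 3,
               tolerance = 1e-6)
  # monotone decreasing between d and c for b > 0
  x <- c(0, 10^seq(-2, 4, by = 0.5))
  fx <- loglogistic(x, b = 1.7, c = 10, d = 95, e = 60)
  expect_true(all(diff(fx) < 0))
  expect_true(all(fx <= 95 & fx >= 10))
  # algebraic equivalence with the exp(b(log x - log e)) form
  xp <- x[x > 0]
  expect_equal(loglogistic(xp, b = 2.2, c = 1, d = 9, e = 35),
               1 + (9 - 1) / (1 + exp(2.2 * (log(xp) - log(35)))))
})

test_that("LL4 parameters are recovered exactly from noiseless 13-dose data", {
  y <- loglogistic(cisplatin_doses, b = 2, c = 10, d = 95, e = 60)
  fit <- fit_dose_response(cisplatin_doses, y)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)[c("b", "c", "d", "e")]),
               c(2, 10, 95, 60), tolerance = 1e-4)
  expect_lt(fit$rse, 1e-6)
  td <- tidy(fit)
  expect_equal(td$term, c("b", "c", "d", "e"))
  expect_false(any(td$fixed))
})

test_that("degenerate and underdetermined inputs are flagged, not fatal", {
  f1 <- fit_dose_response(cisplatin_doses, rep(50, 13))
  expect_false(f1$converged)
  f2 <- fit_dose_response(c(0, 10, 20), c(90, 60, 30))  # < 5 distinct doses
  expect_false(f2$converged)
  expect_match(f2$message, "distinct doses")
})

test_that("nested families agree: LL4 on LL2-generated data finds c~0, d~1", {
  doses <- c(0, 1, 3, 10, 30, 100, 300)
  y <- loglogistic(doses, b = 1.5, c = 0, d = 1, e = 20)
  f2 <- fit_dose_response(doses, y, family = "LL2")
  f4 <- fit_dose_response(doses, y, family = "LL4")
  expect_equal(unname(coef(f2)[["e"]]), 20, tolerance = 1e-6)
  expect_equal(unname(coef(f4)[["c"]]), 0, tolerance = 1e-4)
  expect_equal(unname(coef(f4)[["d"]]), 1, tolerance = 1e-4)
  expect_equal(unname(coef(f4)[["e"]]), 20, tolerance = 1e-3)
})

test_that("scaling all doses by k scales the fitted e by k exactly", {
  y <- loglogistic(cisplatin_doses, b = 2.5, c = 5, d = 90, e = 45)
  for (k in c(0.1, 7)) {
    fit <- fit_dose_response(cisplatin_doses * k, y)
    expect_equal(unname(coef(fit)[["e"]]), 45 * k, tolerance = 1e-6)
  }
})

test_that("estimates converge to truth as noise goes to zero", {
  truth <- c(b = 2, c = 10, d = 95, e = 60)
  range_y <- 85
  for (sdev in c(0, 0.005 * range_y)) {
    sim <- simulate_dose_response_surface(
      times = 1:8, doses = cisplatin_doses,
      params_fun = function(t) truth, noise_sd = sdev, seed = 33)
    fits <- lapply(1:8, function(i)
      fit_dose_response(cisplatin_doses, as.numeric(as.matrix(
        sim$table[i, -1]))))
    e_hat <- vapply(fits, function(f) unname(coef(f)[["e"]]), numeric(1))
    tol <- if (sdev == 0) 1e-4 else 0.1
    expect_equal(mean(e_hat), 60, tolerance = tol)
  }
})

test_that("time-constant truth gives a flat trajectory within 3 SEs", {
  truth <- c(b = 2, c = 10, d = 95, e = 55)
  sim <- simulate_dose_response_surface(
    times = seq(0, 2, by = 0.1), doses = cisplatin_doses,
    params_fun = function(t) truth, noise_sd = 0.4, seed = 17)
  traj <- fit_ic50_over_time(sim$table, sim$layout)
  ok <- traj$converged
  expect_gt(mean(ok), 0.9)
  expect_true(all(abs(traj$ic50[ok] - 55) <= 3 * traj$se[ok]))
})

test_that("trajectory handles strides, corrupted points and short windows", {
  e_fun <- function(t) 80 - 10 * t
  sim <- simulate_dose_response_surface(
    times = seq(0, 2, by = 0.25), doses = cisplatin_doses,
    params_fun = function(t) c(b = 2, c = 10, d = 95, e = e_fun(t)),
    noise_sd = 0, seed = 1)
  # stride covering the whole window -> single fit
  traj1 <- fit_ic50_over_time(sim$table, sim$layout, stride = 1000L)
  expect_equal(nrow(traj1), 1)
  # a NaN at one (time, dose) leaves neighbours untouched
  tab <- sim$table
  tab[[4]][3] <- NaN
  traj <- fit_ic50_over_time(tab, sim$layout)
  expect_equal(attr(traj, "fits")[[3]]$n, 12)      # the corrupted fit
  expect_equal(attr(traj, "fits")[[3]]$n_dropped, 1)
  clean <- fit_ic50_over_time(sim$table, sim$layout)
  expect_equal(traj$ic50[-3], clean$ic50[-3])
  expect_equal(traj$ic50, e_fun(traj$time), tolerance = 1e-4)
  # too few distinct doses is an error before fitting
  few <- simulate_dose_response_surface(
    times = 0:3, doses = c(0, 10, 100),
    params_fun = function(t) c(b = 2, c = 10, d = 95, e = 30))
  expect_error(fit_ic50_over_time(few$table, few$layout), "distinct doses")
})

test_that("fit tidiers expose the IC50 and convergence", {
  y <- loglogistic(cisplatin_doses, b = 2, c = 10, d = 95, e = 60)
  fit <- fit_dose_response(cisplatin_doses, y, time = 2.5)
  g <- glance(fit)
  expect_equal(g$ic50, 60, tolerance = 1e-4)
  expect_equal(g$time, 2.5)
  expect_true(g$converged)
})
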
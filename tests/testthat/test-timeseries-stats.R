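ref_layout <- function() plate_layout(
  well = c("R1", "R2", "S1"), group = c("ref", "ref", "s"),
  role = c("reference", "reference", "sample"))

test_that("reference normalization follows x / m_t * M", {
  tbl <- mk_table(R1 = c(10, 20), R2 = c(12, 20), S1 = c(22, 30))
  out <- normalize_to_reference(tbl, ref_layout(), 100)
  expect_equal(out$S1[1], 22 / 11 * 100)  # hand arithmetic: m_t = 11
  expect_equal((out$R1 + out$R2) / 2, c(100, 100))  # refs hit M exactly
  # a sample equal to the reference mean becomes the constant M
  tbl2 <- mk_table(R1 = c(10, 20), R2 = c(12, 20), S1 = c(11, 20))
  expect_equal(normalize_to_reference(tbl2, ref_layout(), 91.3)$S1,
               c(91.3, 91.3))
  # zero reference mean names the offending time
  tbl3 <- mk_table(R1 = c(10, -5), R2 = c(12, 5), S1 = c(1, 1))
  expect_error(normalize_to_reference(tbl3, ref_layout(), 100), "t = 1")
})

test_that("reference normalization is idempotent", {
  withr::local_seed(4)
  tbl <- mk_table(R1 = runif(6, 80, 95), R2 = runif(6, 80, 95),
                  S1 = runif(6, 40, 95))
  once <- normalize_to_reference(tbl, ref_layout(), 91.3)
  twice <- normalize_to_reference(once, ref_layout(), 91.3)
  expect_equal(as.data.frame(twice), as.data.frame(once))
})

test_that("replicate aggregation gives sample mean and SD pairwise over NAs", {
  lay <- mk_layout(c("A1", "A2", "A3"), "g")
  tbl <- mk_table(A1 = c(1, 1, NA), A2 = c(2, 1, NA), A3 = c(3, 1, NA))
  agg <- aggregate_replicates(tbl, lay)
  expect_equal(agg$g, c(2, 1, NA))             # triplicate mean
  expect_equal(attr(agg, "sd")$g, c(1, 0, NA)) # sample SD (n - 1), SD 0 ties
  # group of size 1 is flagged and gets SD 0
  expect_warning(
    agg1 <- aggregate_replicates(mk_table(A1 = c(1, 2)),
                                 mk_layout("A1", "solo")),
    "size 1")
  expect_equal(attr(agg1, "sd")$solo, c(0, 0))
})

test_that("aggregation of the standard plate yields one curve per dose", {
  sim <- simulate_treatment_experiment(sim_config(seed = 8, t_end = 0.5,
                                                  dt = 0.05))
  agg <- aggregate_replicates(sim$table, sim$layout)
  expect_equal(length(measure_names(agg)), 14)  # 13 dose groups + medium
  expect_true(all(attr(agg, "sd")$medium >= 0))
})

test_that("aggregation commutes with value scaling", {
  withr::local_seed(12)
  lay <- mk_layout(c("A1", "A2", "B1"), c("a", "a", "b"))
  tbl <- mk_table(A1 = rnorm(5), A2 = rnorm(5), B1 = rnorm(5))
  a1 <- suppressWarnings(aggregate_replicates(scale_values(tbl, 3), lay))
  a2 <- suppressWarnings(aggregate_replicates(tbl, lay))
  expect_equal(a1$a, 3 * a2$a)
  expect_equal(a1$b, 3 * a2$b)
})

test_that("moving-average smoothing drops (n-1)/2 points per end", {
  tbl <- mk_table(A = c(1, 2, 3, 4, 5))
  sm <- smooth_table(tbl, 3)
  expect_equal(sm$A, c(2, 3, 4))        # hand means
  expect_equal(sm$time, tbl$time[2:4])
  expect_error(smooth_table(tbl, 4), "odd")
  # n = 11 loses 5 points at each end
  tbl2 <- mk_table(A = seq_len(30) + 0.0)
  expect_equal(nrow(smooth_table(tbl2, 11)), 30 - 10)
  # constants stay constant, linear series stay the same line
  expect_equal(smooth_table(mk_table(A = rep(7, 9)), 5)$A, rep(7, 5))
  lin <- smooth_table(tbl2, 7)
  expect_equal(lin$A, lin$time + 1)
})

test_that("smoothing preserves the mean of a periodic series over periods", {
  t <- 0:23
  y <- sin(2 * pi * t / 6)
  sm <- smooth_table(mk_table(A = y, time = t + 0.0), 7)
  # any 6 consecutive smoothed points average to ~ the global mean (0)
  expect_lt(abs(mean(sm$A[1:6])), 1e-12)
})

test_that("windowed slope is exact on linear data and matches closed form", {
  tbl <- mk_table(A = 2 * (0:10) + 5, time = 0:10 + 0.0)
  sl <- windowed_slope(tbl, 3)
  expect_equal(sl$A, rep(2, 5))
  expect_equal(max(attr(sl, "residual")$A), 0)
  expect_equal(nrow(sl), 11 - 6)  # n lost each end
  # constant series: slope 0
  expect_equal(windowed_slope(mk_table(A = rep(3, 7)), 2)$A, rep(0, 3))
  # closed-form 3-point check against lm()
  tb3 <- mk_table(A = c(0, 1, 4), time = c(0, 1, 2))
  sl3 <- windowed_slope(tb3, 1)
  fit <- lm(c(0, 1, 4) ~ c(0, 1, 2))
  expect_equal(sl3$A, unname(coef(fit)[2]))        # slope 2
  expect_equal(sl3$A, 2)
  expect_equal(attr(sl3, "residual")$A, summary(fit)$sigma)
  expect_error(windowed_slope(tb3, 2), "short")
})

test_that("windowed slope agrees with brute-force per-window OLS to 1e-12", {
  withr::local_seed(101)
  t <- cumsum(runif(50, 0.5, 1.5))      # irregular spacing
  y <- rnorm(50, sd = 5)
  tbl <- mk_table(A = y, time = t)
  for (n in c(1, 4, 10)) {
    sl <- windowed_slope(tbl, n)
    res <- attr(sl, "residual")$A
    for (k in seq_along(sl$time)) {
      idx <- k:(k + 2 * n)
      fit <- lm(y[idx] ~ t[idx])
      expect_equal(sl$A[k], unname(coef(fit)[2]), tolerance = 1e-12)
      expect_equal(res[k], summary(fit)$sigma, tolerance = 1e-12)
    }
  }
})

test_that("slope of a cumulative sum approximates the original series", {
  t <- seq(0, 2 * pi, length.out = 200)
  dt <- t[2] - t[1]
  y <- sin(t)
  antider <- cumsum(y) * dt
  sl <- windowed_slope(mk_table(A = antider, time = t), 3)
  mid <- which(sl$time > 1 & sl$time < 5)
  expect_lt(max(abs(sl$A[mid] - sin(sl$time)[mid])), 0.05)
})

test_that("missing values pass through smoothing and slope as gaps", {
  tbl <- mk_table(A = c(1, 2, NA, 4, 5, 6, 7))
  sm <- smooth_table(tbl, 3)
  expect_true(all(is.na(sm$A[1:3])))    # windows touching the NA
  expect_false(anyNA(sm$A[4:5]))
  sl <- windowed_slope(tbl, 1)
  expect_true(anyNA(sl$A))
  expect_false(anyNA(sl$A[4:5]))
})
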
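updown_seq <- function(filament_g, response,
                       fils = c(0.6, 1, 1.4, 2, 4, 6, 8, 10, 15, 26)) {
  out <- tibble::tibble(filament_g = filament_g, response = response)
  attr(out, "filament_set") <- fils
  out
}

test_that("one-sided sequences are censored at the filament-set bounds", {
  hi <- updown_seq(c(2, 4, 6, 8, 10, 15, 26), rep("0", 7))
  r_hi <- estimate_threshold(hi)
  expect_equal(r_hi$threshold_g, 26)
  expect_equal(r_hi$censored, "high")

  lo <- updown_seq(c(2, 1.4, 1, 0.6), rep("X", 4))
  r_lo <- estimate_threshold(lo)
  expect_equal(r_lo$threshold_g, 0.6)
  expect_equal(r_lo$censored, "low")
})

test_that("a symmetric alternating pattern gives the geometric midpoint", {
  # equal numbers of 0 at 8 g and X at 10 g: the Dixon/probit likelihood is
  # maximised exactly midway in log units, so the threshold is sqrt(8 * 10)
  s <- updown_seq(c(8, 10, 8, 10, 8, 10),
                  c("0", "X", "0", "X", "0", "X"))
  r <- estimate_threshold(s)
  expect_equal(r$censored, "none")
  expect_equal(r$threshold_g, sqrt(80), tolerance = 1e-6)
  # formula identity
  expect_equal(r$threshold_g, 10^(r$x_f + r$k * r$delta) / 1e4,
               tolerance = 1e-9)
})

test_that("the formula identity holds for simulated sequences", {
  for (s in 1:30) {
    seqd <- simulate_updown_trials(runif(1, 1, 20), 5, seed = 200 + s)
    r <- estimate_threshold(seqd)
    if (r$censored == "none") {
      expect_equal(r$threshold_g, 10^(r$x_f + r$k * r$delta) / 1e4,
                   tolerance = 1e-9)
    }
    expect_gte(r$threshold_g, 0.6 - 1e-9)
    expect_lte(r$threshold_g, 26 + 1e-9)
  }
})

test_that("up-down rule violations are reported with the offending step", {
  bad <- updown_seq(c(2, 6), c("0", "0"))  # 2 g then a jump of two filaments
  expect_error(estimate_threshold(bad), "step 1")
})

test_that("Hargreaves latency is the trial mean, bounded by the cut-off", {
  expect_equal(hargreaves_latency(c(20.48, 20.48, 20.48)), 20.48)
  expect_equal(hargreaves_latency(c(9, 10, 11)), 10)
  expect_equal(hargreaves_latency(7.5), 7.5)
  expect_error(hargreaves_latency(c(10, 21)), "cut-off")
  expect_error(hargreaves_latency(c(1, 2, 3, 4)))
})

test_that("mean estimated threshold is nondecreasing in the true threshold", {
  mean_est <- vapply(c(2, 4, 8), function(thr) {
    mean(vapply(1:150, function(s)
      estimate_threshold(simulate_updown_trials(thr, 5,
                                                seed = 7000 + s))$threshold_g,
      0))
  }, 0)
  expect_true(all(diff(mean_est) > 0))
})

test_that("the up-down estimator recovers thresholds across the working range", {
  for (thr in c(1, 4, 15)) {
    est <- vapply(1:200, function(s)
      estimate_threshold(simulate_updown_trials(thr, 5,
                                                seed = 9000 + s))$threshold_g,
      0)
    expect_lt(abs(stats::median(est) - thr) / thr, 0.20)
  }
})
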
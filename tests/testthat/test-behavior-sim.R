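test_that("extreme thresholds produce censored one-sided staircases", {
  # threshold far above the strongest filament: all-negative, ends at 26 g
  s_hi <- simulate_updown_trials(1000, psychometric_slope = Inf, seed = 1)
  expect_true(all(s_hi$response == "0"))
  expect_equal(s_hi$filament_g[nrow(s_hi)], 26)
  # threshold far below the weakest: all-positive, ends at 0.6 g
  s_lo <- simulate_updown_trials(0.01, psychometric_slope = Inf, seed = 1)
  expect_true(all(s_lo$response == "X"))
  expect_equal(s_lo$filament_g[nrow(s_lo)], 0.6)
})

test_that("a step psychometric function walks deterministically around the boundary", {
  # threshold 3 g sits strictly between the 2 g and 4 g filaments: the
  # ascending phase climbs to the boundary, then the staircase alternates
  s <- simulate_updown_trials(3, psychometric_slope = Inf, seed = 99)
  expect_equal(s$filament_g, c(0.6, 1, 1.4, 2, 4, 2, 4, 2, 4))
  expect_equal(s$response, c("0", "0", "0", "0", "X", "0", "X", "0", "X"))
  # starting mid-range reproduces the pure alternation
  s2 <- simulate_updown_trials(3, psychometric_slope = Inf, start_g = 2,
                               seed = 99)
  expect_equal(s2$filament_g, c(2, 4, 2, 4, 2, 4))
  expect_equal(s2$response, c("0", "X", "0", "X", "0", "X"))
})

test_that("staircases obey the up-down transition rule", {
  fils <- c(0.6, 1, 1.4, 2, 4, 6, 8, 10, 15, 26)
  for (s in 1:25) {
    seqd <- simulate_updown_trials(runif(1, 1, 20), 5, seed = s)
    idx <- match(seqd$filament_g, fils)
    for (i in seq_len(nrow(seqd) - 1)) {
      expected <- if (seqd$response[i] == "X") max(idx[i] - 1, 1) else
        min(idx[i] + 1, length(fils))
      expect_equal(idx[i + 1], expected)
    }
  }
  expect_error(simulate_updown_trials(4, 5, filament_set = numeric()),
               "empty")
  expect_error(simulate_updown_trials(4, 5, filament_set = c(2, 1)),
               "ascending")
})

test_that("Hargreaves trials respect the cut-off and recover the mean", {
  expect_equal(simulate_hargreaves_trials(30, 0, seed = 1),
               c(20.48, 20.48, 20.48))
  expect_equal(simulate_hargreaves_trials(9, 0, seed = 1), c(9, 9, 9))
  lat <- simulate_hargreaves_trials(10, 1, n_trials = 1e4, seed = 2)
  expect_true(all(lat <= 20.48))
  expect_lt(abs(mean(lat) - 10), 2 * 1 / sqrt(1e4))
})

test_that("behavioural cohorts are deterministic in the seed", {
  cfg <- default_timecourse(behavior_n = 3)
  b1 <- simulate_behavior_cohort(cfg, 21, seed = 5)
  b2 <- simulate_behavior_cohort(cfg, 21, seed = 5)
  expect_identical(b1, b2)
  b3 <- simulate_behavior_cohort(cfg, 21, seed = 6)
  expect_false(identical(b1$vf_trials, b3$vf_trials))
})
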
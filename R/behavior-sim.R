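#' Simulate a von Frey up-down staircase
#'
#' Generates one up-down sequence over the study's filament set. The
#' animal's withdrawal probability follows a logistic psychometric function
#' of log10 filament force with P(withdraw) = 0.5 at the true threshold.
#' Testing starts at `start_g` — by default the weakest filament, matching
#' the protocol of presenting hairs serially in ascending order of strength
#' until the first withdrawal — then moves one filament down after a
#' withdrawal ("X") and one up after no withdrawal ("0"), and stops after
#' four presentations beyond the first reversal. A "0" at the strongest filament or an "X" at the weakest stops
#' the staircase immediately (the threshold is then censored at the
#' corresponding bound when the whole sequence is one-sided).
#'
#' @param true_threshold_g true 50% withdrawal threshold in grams.
#' @param psychometric_slope logistic slope per log10 gram; larger is
#'   steeper. `Inf` gives a deterministic step function.
#' @param filament_set ascending filament forces in grams.
#' @param start_g starting filament (snapped to the nearest set member).
#' @param post_reversal number of presentations recorded after the first
#'   reversal before stopping.
#' @param seed integer seed.
#' @return an object of class `dh_vf_sequence`: a tibble with columns
#'   `trial`, `filament_g`, `response` (`"X"` withdrawal / `"0"` none) and
#'   attribute `filament_set`.
#' @examples
#' simulate_updown_trials(4, psychometric_slope = 5, seed = 1)
#' @export
simulate_updown_trials <- function(true_threshold_g,
                                   psychometric_slope = 5,
                                   filament_set = c(0.6, 1, 1.4, 2, 4, 6,
                                                    8, 10, 15, 26),
                                   start_g = 0.6,
                                   post_reversal = 4,
                                   seed = 1L) {
  if (length(filament_set) == 0) stop("empty filament set", call. = FALSE)
  if (is.unsorted(filament_set, strictly = TRUE)) {
    stop("filament_set must be sorted ascending", call. = FALSE)
  }
  stopifnot(psychometric_slope > 0, true_threshold_g > 0)
  idx <- which.min(abs(filament_set - start_g))
  lthr <- log10(true_threshold_g)

  withdraw_prob <- function(f) {
    if (is.infinite(psychometric_slope)) as.numeric(log10(f) > lthr)
    else stats::plogis(psychometric_slope * (log10(f) - lthr))
  }

  filament <- numeric(0)
  response <- character(0)
  withr_seed(seed, {
    reversal_seen <- FALSE
    after_reversal <- 0L
    repeat {
      f <- filament_set[idx]
      wd <- stats::runif(1) < withdraw_prob(f)
      filament <- c(filament, f)
      response <- c(response, if (wd) "X" else "0")
      n <- length(response)
      if (reversal_seen) after_reversal <- after_reversal + 1L
      if (n > 1 && response[n] != response[n - 1]) reversal_seen <- TRUE
      if (reversal_seen && after_reversal >= post_reversal) break
      if (wd && idx == 1L) break                      # withdrawal at weakest
      if (!wd && idx == length(filament_set)) break   # none at strongest
      idx <- idx + if (wd) -1L else 1L
      if (n >= 30L) break  # safety cap, never reached under the up-down rule
    }
  })
  out <- tibble::tibble(trial = seq_along(filament),
                        filament_g = filament,
                        response = response)
  attr(out, "filament_set") <- filament_set
  class(out) <- c("dh_vf_sequence", class(out))
  out
}

#' Simulate Hargreaves radiant-heat withdrawal trials
#'
#' Draws `n_trials` withdrawal latencies around the true latency with
#' Gaussian trial-to-trial noise, truncated at the apparatus cut-off that
#' prevents tissue damage.
#'
#' @param true_latency_s true withdrawal latency in seconds.
#' @param trial_sd_s trial-to-trial standard deviation in seconds.
#' @param n_trials number of trials (the study averages 3).
#' @param cutoff_s apparatus cut-off in seconds.
#' @param seed integer seed.
#' @return numeric vector of `n_trials` latencies, each `<= cutoff_s`.
#' @examples
#' simulate_hargreaves_trials(30, 0, seed = 1)  # all at the 20.48 s cut-off
#' @export
simulate_hargreaves_trials <- function(true_latency_s, trial_sd_s = 1.5,
                                       n_trials = 3, cutoff_s = 20.48,
                                       seed = 1L) {
  stopifnot(true_latency_s > 0, trial_sd_s >= 0, n_trials >= 1)
  withr_seed(seed, {
    lat <- stats::rnorm(n_trials, true_latency_s, trial_sd_s)
  })
  pmin(pmax(lat, 0.01), cutoff_s)
}

#' Simulate one day's behavioural cohort
#'
#' Generates von Frey staircases and Hargreaves trials for sham and cuff
#' animals at one post-surgery day, with true endpoints set by the
#' time-course configuration (cuff truths are the configured percent of the
#' sham baseline). Animal-level sub-seeds derive deterministically from
#' `seed`.
#'
#' @param config a [timecourse_config()] object.
#' @param day post-surgery day (must be in `config$days`).
#' @param seed integer seed for the whole cohort.
#' @param sides which paws to test.
#' @return list of two tibbles: `vf_trials` (`animal`, `group`, `side`,
#'   `trial`, `filament_g`, `response`) and `hg_trials` (`animal`, `group`,
#'   `side`, `trial`, `latency_s`), plus `truth` (per animal true
#'   endpoints).
#' @export
simulate_behavior_cohort <- function(config, day, seed = 1L,
                                     sides = c("ipsilateral", "contralateral")) {
  stopifnot(inherits(config, "dh_timecourse"), day %in% config$days)
  groups <- c(rep("sham", config$behavior_n), rep("cuff", config$behavior_n))
  animals <- sprintf("%s_%02d", groups, c(seq_len(config$behavior_n),
                                          seq_len(config$behavior_n)))
  vf <- list(); hg <- list(); truth <- list()
  for (a in seq_along(animals)) {
    for (s in sides) {
      vf_thr <- config$vf_baseline_g *
        lookup_behavior_pct(config, day, groups[a], s, "von_frey") / 100
      hg_lat <- config$hg_baseline_s *
        lookup_behavior_pct(config, day, groups[a], s, "hargreaves") / 100
      s_idx <- match(s, c("ipsilateral", "contralateral"))
      seq_vf <- simulate_updown_trials(
        vf_thr, config$psychometric_slope,
        seed = derive_seed(seed, 11L, a, s_idx))
      lat <- simulate_hargreaves_trials(
        hg_lat, config$hg_trial_sd_s,
        seed = derive_seed(seed, 13L, a, s_idx))
      vf[[length(vf) + 1]] <- dplyr::mutate(seq_vf, animal = animals[a],
                                            group = groups[a], side = s,
                                            .before = 1)
      hg[[length(hg) + 1]] <- tibble::tibble(
        animal = animals[a], group = groups[a], side = s,
        trial = seq_along(lat), latency_s = lat)
      truth[[length(truth) + 1]] <- tibble::tibble(
        animal = animals[a], group = groups[a], side = s, day = day,
        true_vf_threshold_g = vf_thr, true_hg_latency_s = hg_lat)
    }
  }
  list(vf_trials = dplyr::bind_rows(vf),
       hg_trials = dplyr::bind_rows(hg),
       truth = dplyr::bind_rows(truth))
}
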
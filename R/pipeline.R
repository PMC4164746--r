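#' Pipeline commands: simulate, quantify, analyze
#'
#' Thin orchestration layer over the package's stages, mirroring the three
#' steps a study re-analysis takes: write a synthetic dataset, quantify its
#' images, and run the cohort statistics. Each command writes its effective
#' configuration next to its outputs and is deterministic for a fixed seed.
#'
#' @param config a [timecourse_config()] object (default: the packaged
#'   neuropathic time-course).
#' @param seed integer seed.
#' @param out_dir dataset directory to create.
#' @param days days to simulate.
#' @param ... passed to [simulate_cohort()].
#' @return `run_simulate()`: the manifest (invisibly); `run_quantify()`:
#'   the density tibble (also written as CSV); `run_analyze()`: the
#'   [analyze_cohort()] results list (also written as CSV/JSON).
#' @export
run_simulate <- function(config = default_timecourse(), seed = 1L, out_dir,
                         days = config$days, ...) {
  simulate_cohort(config, seed = seed, out_dir = out_dir, days = days, ...)
}

#' @rdname run_simulate
#' @param dataset_dir dataset directory written by `run_simulate()`.
#' @param params a [quant_params()] list.
#' @param out_csv where to write the density records.
#' @export
run_quantify <- function(dataset_dir, params = quant_params(),
                         out_csv = file.path(dataset_dir, "densities.csv"),
                         ...) {
  records <- quantify_dataset(dataset_dir, params = params, ...)
  utils::write.csv(records, out_csv, row.names = FALSE)
  invisible(records)
}

#' @rdname run_simulate
#' @param density_csv density CSV from `run_quantify()` (or an in-memory
#'   tibble).
#' @param behavior_scores optional scored behaviour table or `NULL`.
#' @param out_results directory for the results bundle.
#' @export
run_analyze <- function(density_csv, behavior_scores = NULL, out_results,
                        ...) {
  records <- if (is.character(density_csv)) {
    tibble::as_tibble(utils::read.csv(density_csv))
  } else density_csv
  res <- analyze_cohort(records, behavior_scores = behavior_scores, ...)
  dir.create(out_results, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$normalized,
                   file.path(out_results, "normalized.csv"), row.names = FALSE)
  utils::write.csv(res$comparisons,
                   file.path(out_results, "comparisons.csv"), row.names = FALSE)
  if (nrow(res$correlations %||% tibble::tibble()) > 0) {
    utils::write.csv(res$correlations,
                     file.path(out_results, "correlations.csv"),
                     row.names = FALSE)
  }
  summary <- list(
    normalized = res$normalized,
    correlations = res$correlations,
    n_records = nrow(records)
  )
  jsonlite::write_json(summary, file.path(out_results, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' End-to-end density recovery for one day and endpoint
#'
#' Runs the full synthetic pipeline for one post-surgery day (cohort
#' simulation, rendering, quantification, animal-level averaging,
#' percent-of-sham normalisation) and returns the recovered cuff
#' ipsilateral mean as a percent of sham for each lamina x marker.
#'
#' @param day post-surgery day.
#' @param seed cohort seed.
#' @param config a [timecourse_config()]; the packaged default encodes the
#'   reported time-course.
#' @param ... passed to [simulate_quantify_day()].
#' @return tibble with `lamina`, `marker`, `recovered_pct` (cuff
#'   ipsilateral mean percent of sham), `true_pct` (configured), and
#'   `n_animals`.
#' @export
recover_density_day <- function(day, seed = 1L,
                                config = default_timecourse(), ...) {
  records <- simulate_quantify_day(config, day, seed = seed, ...)
  per_animal <- animal_means(records)
  norm <- normalize_to_sham(per_animal, endpoint_cols = c("lamina", "marker"))
  cuff <- norm[norm$group == "cuff" & norm$side == "ipsilateral", ]
  cuff$recovered_pct <- cuff$mean_pct_of_sham
  cuff$true_pct <- mapply(function(l, m)
    lookup_pct(config, day, "cuff", "ipsilateral", l, m),
    cuff$lamina, cuff$marker)
  cuff$n_animals <- cuff$n_animals
  cuff[, c("lamina", "marker", "recovered_pct", "true_pct", "n_animals")]
}

#' End-to-end behavioural recovery for one day
#'
#' Simulates one day's behavioural cohort, scores it (up-down estimator,
#' Hargreaves trial average) and returns the cuff ipsilateral means as a
#' percent of sham.
#'
#' @inheritParams recover_density_day
#' @return tibble with `endpoint`, `recovered_pct`, `true_pct`,
#'   `n_animals`.
#' @export
recover_behavior_day <- function(day, seed = 1L,
                                 config = default_timecourse()) {
  beh <- simulate_behavior_cohort(config, day, seed = seed)
  scores <- score_behavior(beh)
  scores$day <- day
  norm <- normalize_to_sham(scores, endpoint_cols = "endpoint")
  cuff <- norm[norm$group == "cuff" & norm$side == "ipsilateral", ]
  cuff$recovered_pct <- cuff$mean_pct_of_sham
  cuff$true_pct <- vapply(cuff$endpoint, function(e)
    lookup_behavior_pct(config, day, "cuff", "ipsilateral", e), 0)
  cuff[, c("endpoint", "recovered_pct", "true_pct", "n_animals")]
}
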
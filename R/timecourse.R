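#' Study time-course configuration
#'
#' Bundles everything the cohort simulator needs: the post-surgery days, the
#' per-condition true densities (as percent of sham) for each side, lamina
#' and marker, the behavioural truths (von Frey 50% threshold, Hargreaves
#' latency), cohort sizes, baseline absolute values, and the variance
#' components of the generative model.
#'
#' The packaged default ([default_timecourse()]) encodes the reported
#' neuropathic time-course: IB4 terminal density in the lamina-II lesion
#' zone falls to 1.5% of sham at day 21 and recovers only to 52.1% by day
#' 56; GAD65 density in the same zone falls to 34.1% at day 21 and reaches
#' 72% at day 56; GAD65 in lamina I reaches its 63.1% minimum at day 21;
#' the von Frey threshold bottoms out at 16.3% of sham at day 21; the
#' Hargreaves latency reaches 70.1% of sham at day 28. Sham percentages are
#' 100 by construction.
#'
#' @param days ordered vector of post-surgery days.
#' @param histology_pct tibble with columns `day`, `group`, `side`,
#'   `lamina`, `marker`, `pct` (percent of sham). Lamina-II percentages
#'   apply within the lesion zone's medio-lateral interval; lamina-I
#'   percentages apply across the band.
#' @param behavior_pct tibble with columns `day`, `group`, `side`,
#'   `endpoint` (`"von_frey"`, `"hargreaves"`), `pct`.
#' @param sham_n,cuff_n histology cohort sizes (animals per group per day).
#' @param behavior_n behavioural cohort size per group.
#' @param sections_per_animal tissue sections quantified per animal.
#' @param baseline_density named list of sham absolute densities per
#'   100 um^2, `baseline_density[[marker]][[lamina]]`.
#' @param mean_area_um2 per-channel mean single-varicosity areas.
#' @param area_cv coefficient of variation of single-punctum area.
#' @param vf_baseline_g,hg_baseline_s sham behavioural truths.
#' @param psychometric_slope logistic slope (per log10 gram) of the
#'   simulated withdrawal psychometric function.
#' @param hg_trial_sd_s trial-to-trial SD of Hargreaves latencies (s).
#' @param animal_cv,section_cv multiplicative log-normal variability of true
#'   density between animals and between sections within animal.
#' @param coupling fraction (0-1) of the animal-level log-variance shared
#'   between the IB4 and GAD65 channels; tunes the cross-marker density
#'   correlation without changing the marginals.
#' @return an object of class `dh_timecourse` (a named list).
#' @seealso [default_timecourse()], [simulate_cohort()]
#' @export
timecourse_config <- function(days = c(5, 7, 10, 14, 21, 28, 42, 56),
                              histology_pct,
                              behavior_pct,
                              sham_n = 5, cuff_n = 6,
                              behavior_n = 10,
                              sections_per_animal = 6,
                              baseline_density = list(
                                IB4 = c(LI = 4, LII = 20),
                                GAD65 = c(LI = 12, LII = 15)),
                              mean_area_um2 = c(IB4 = 0.3, GAD65 = 0.2),
                              area_cv = 0.5,
                              vf_baseline_g = 15,
                              hg_baseline_s = 10,
                              psychometric_slope = 5,
                              hg_trial_sd_s = 1.5,
                              animal_cv = 0.15,
                              section_cv = 0.10,
                              coupling = 0.6) {
  stopifnot(all(histology_pct$pct >= 0), all(behavior_pct$pct >= 0),
            sections_per_animal >= 1, coupling >= 0, coupling <= 1)
  sham_rows <- histology_pct$group == "sham"
  if (any(abs(histology_pct$pct[sham_rows] - 100) > 1e-9)) {
    stop("sham histology percentages must be 100 by construction", call. = FALSE)
  }
  structure(
    list(days = days,
         histology_pct = histology_pct,
         behavior_pct = behavior_pct,
         sham_n = sham_n, cuff_n = cuff_n,
         behavior_n = behavior_n,
         sections_per_animal = sections_per_animal,
         baseline_density = baseline_density,
         mean_area_um2 = mean_area_um2,
         area_cv = area_cv,
         vf_baseline_g = vf_baseline_g,
         hg_baseline_s = hg_baseline_s,
         psychometric_slope = psychometric_slope,
         hg_trial_sd_s = hg_trial_sd_s,
         animal_cv = animal_cv,
         section_cv = section_cv,
         coupling = coupling),
    class = "dh_timecourse"
  )
}

#' Packaged default neuropathic time-course
#'
#' Percent-of-sham truths per day for the cuff (neuropathic) group,
#' encoding the reported minima/recovery values at the days the study
#' states them and smooth interpolations elsewhere. Sham is 100 throughout;
#' contralateral sides are 100 except GAD65 in lamina I, where the
#' ipsilateral trend is mirrored (the study observed a similar loss on both
#' sides in lamina I).
#'
#' @inheritParams timecourse_config
#' @param ... passed on to [timecourse_config()].
#' @return a `dh_timecourse` object.
#' @export
default_timecourse <- function(...) {
  days <- c(5, 7, 10, 14, 21, 28, 42, 56)
  cuff_ipsi <- tibble::tribble(
    ~lamina, ~marker, ~pcts,
    "LII", "IB4",   c(60, 45, 25, 10, 1.5, 10, 30, 52.1),
    "LII", "GAD65", c(90, 85, 65, 50, 34.1, 45, 60, 72),
    "LI",  "GAD65", c(92, 88, 78, 70, 63.1, 72, 90, 95),
    "LI",  "IB4",   c(100, 100, 100, 100, 100, 100, 100, 100)
  )
  cuff_ipsi <- tidyr::unnest(
    dplyr::mutate(cuff_ipsi, day = list(days)),
    c(day, pcts))
  names(cuff_ipsi)[names(cuff_ipsi) == "pcts"] <- "pct"
  cuff_ipsi$group <- "cuff"
  cuff_ipsi$side <- "ipsilateral"

  cuff_contra <- cuff_ipsi
  cuff_contra$side <- "contralateral"
  cuff_contra$pct <- ifelse(cuff_contra$lamina == "LI" &
                              cuff_contra$marker == "GAD65",
                            cuff_contra$pct, 100)

  grid <- tidyr::expand_grid(day = days,
                             side = c("ipsilateral", "contralateral"),
                             lamina = c("LI", "LII"),
                             marker = c("IB4", "GAD65"))
  sham <- dplyr::mutate(grid, group = "sham", pct = 100)
  histology <- dplyr::bind_rows(
    sham,
    dplyr::select(cuff_ipsi, day, side, lamina, marker, group, pct),
    dplyr::select(cuff_contra, day, side, lamina, marker, group, pct)
  )

  beh_ipsi <- tibble::tibble(
    day = rep(days, 2),
    endpoint = rep(c("von_frey", "hargreaves"), each = length(days)),
    pct = c(c(80, 65, 45, 30, 16.3, 25, 60, 100),
            c(92, 88, 84, 80, 75, 70.1, 80, 100))
  )
  behavior <- dplyr::bind_rows(
    dplyr::mutate(beh_ipsi, group = "cuff", side = "ipsilateral"),
    tidyr::expand_grid(day = days, endpoint = c("von_frey", "hargreaves"),
                       group = "cuff", side = "contralateral", pct = 100),
    tidyr::expand_grid(day = days, endpoint = c("von_frey", "hargreaves"),
                       group = "sham", side = c("ipsilateral", "contralateral"),
                       pct = 100)
  )
  timecourse_config(days = days, histology_pct = histology,
                    behavior_pct = behavior, ...)
}

#' @export
print.dh_timecourse <- function(x, ...) {
  cat("<dh_timecourse> days ", paste(x$days, collapse = ", "),
      "; ", x$sham_n, " sham + ", x$cuff_n, " cuff animals x ",
      x$sections_per_animal, " sections; behaviour n = ", x$behavior_n,
      "/group\n", sep = "")
  invisible(x)
}

# look up the configured percent of sham for one condition
lookup_pct <- function(config, day, group, side, lamina, marker) {
  h <- config$histology_pct
  hit <- h$day == day & h$group == group & h$side == side &
    h$lamina == lamina & h$marker == marker
  if (!any(hit)) {
    stop(sprintf("no configured percentage for day %s %s %s %s %s",
                 day, group, side, lamina, marker), call. = FALSE)
  }
  h$pct[which(hit)[1]]
}

lookup_behavior_pct <- function(config, day, group, side, endpoint) {
  b <- config$behavior_pct
  hit <- b$day == day & b$group == group & b$side == side &
    b$endpoint == endpoint
  if (!any(hit)) {
    stop(sprintf("no configured behavioural percentage for day %s %s %s %s",
                 day, group, side, endpoint), call. = FALSE)
  }
  b$pct[which(hit)[1]]
}
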
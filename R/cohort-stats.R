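#' Average section-level density records to one value per animal
#'
#' The study's unit of analysis is the animal: the six sections quantified
#' per animal are averaged before any statistic.
#'
#' @param records density records from [simulate_quantify_day()] or
#'   [quantify_dataset()].
#' @return tibble with one row per animal x day x side x lamina x marker:
#'   `value` (mean density per 100 um^2 across sections), `n_sections`, and
#'   `true_density` (mean across sections) when present.
#' @export
animal_means <- function(records) {
  has_truth <- "true_density" %in% names(records)
  records |>
    dplyr::group_by(animal, group, day, side, lamina, marker) |>
    dplyr::summarise(
      value = mean(density),
      n_sections = dplyr::n(),
      true_density = if (has_truth) mean(true_density) else NA_real_,
      .groups = "drop")
}

#' Normalise per-animal endpoints to matched sham controls
#'
#' Expresses every animal's endpoint as a percentage of the same-day,
#' same-side (and same lamina/marker or behavioural endpoint) sham mean:
#' cuff ipsilateral values are divided by the sham ipsilateral mean, cuff
#' contralateral by the sham contralateral mean. Statistics are *not* run
#' on these percentages — [compare_groups()] takes absolute values — the
#' normalised series is the reporting scale only.
#'
#' @param per_animal tibble with one row per animal and columns `animal`,
#'   `group` (`"sham"`/`"cuff"`), `day`, `side`, `value`, plus the endpoint
#'   identifiers in `endpoint_cols`.
#' @param endpoint_cols columns that identify an endpoint stratum
#'   (e.g. `c("lamina", "marker")` for histology, `"endpoint"` for
#'   behaviour).
#' @return an object of class `dh_normalized`: tibble with one row per
#'   day x group x side x endpoint: `mean_pct_of_sham`, `sem_pct`,
#'   `n_animals`.
#' @export
normalize_to_sham <- function(per_animal,
                              endpoint_cols = c("lamina", "marker")) {
  stopifnot(all(c("animal", "group", "day", "side", "value") %in%
                  names(per_animal)),
            all(endpoint_cols %in% names(per_animal)))
  keys <- c("day", "side", endpoint_cols)
  sham_means <- per_animal |>
    dplyr::filter(group == "sham") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(sham_mean = mean(value), .groups = "drop")

  joined <- dplyr::left_join(per_animal, sham_means, by = keys)
  missing <- joined[is.na(joined$sham_mean), keys]
  if (nrow(missing) > 0) {
    first <- missing[1, ]
    stop("no sham animals for stratum: ",
         paste(names(first), unlist(first), sep = "=", collapse = ", "),
         call. = FALSE)
  }
  if (any(joined$sham_mean == 0)) {
    stop("sham mean is zero in at least one stratum; cannot normalise",
         call. = FALSE)
  }
  out <- joined |>
    dplyr::mutate(pct = 100 * value / sham_mean) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys[1], "group",
                                                  keys[-1])))) |>
    dplyr::summarise(
      mean_pct_of_sham = mean(pct),
      sem_pct = stats::sd(pct) / sqrt(dplyr::n()),
      n_animals = dplyr::n(), .groups = "drop")
  class(out) <- c("dh_normalized", class(out))
  out
}

#' Group comparisons on absolute values
#'
#' Implements the study's testing scheme on absolute (un-normalised)
#' per-animal values:
#'
#' * `design = "histology"`: per day and endpoint, an unpaired two-sided
#'   t-test of sham vs cuff ipsilateral values, and a paired two-sided
#'   t-test of ipsilateral vs contralateral values within cuff animals
#'   (each equivalent to a one-way ANOVA with two groups).
#' * `design = "behavior"`: a two-way (group x day) ANOVA per endpoint on
#'   ipsilateral values, followed by per-day sham-vs-cuff contrasts with
#'   Bonferroni correction across days.
#'
#' Degenerate strata (fewer than two animals in a cell) are skipped with a
#' warning.
#'
#' @param per_animal per-animal absolute values (see [normalize_to_sham()]
#'   for the required columns).
#' @param design `"histology"` or `"behavior"`.
#' @param endpoint_cols endpoint stratum columns.
#' @return an object of class `dh_comparisons`: a tibble with `comparison`,
#'   `day`, the endpoint columns, `estimate` (mean difference), `statistic`,
#'   `df`, `p_value`, `p_adjusted`, `method`, `significant`
#'   (at adjusted p < 0.05).
#' @export
compare_groups <- function(per_animal,
                           design = c("histology", "behavior"),
                           endpoint_cols = c("lamina", "marker")) {
  design <- match.arg(design)
  res <- if (design == "histology") {
    compare_histology(per_animal, endpoint_cols)
  } else {
    compare_behavior(per_animal, endpoint_cols)
  }
  res$significant <- !is.na(res$p_adjusted) & res$p_adjusted < 0.05
  class(res) <- c("dh_comparisons", class(res))
  res
}

compare_histology <- function(per_animal, endpoint_cols) {
  strata <- per_animal |>
    dplyr::distinct(dplyr::across(dplyr::all_of(c("day", endpoint_cols))))
  out <- list()
  for (i in seq_len(nrow(strata))) {
    st <- strata[i, ]
    d <- dplyr::semi_join(per_animal, st, by = names(st))
    sham_ipsi <- d$value[d$group == "sham" & d$side == "ipsilateral"]
    cuff <- d[d$group == "cuff", ]
    cuff_ipsi <- cuff$value[cuff$side == "ipsilateral"]
    # sham vs cuff, ipsilateral, unpaired
    if (length(sham_ipsi) >= 2 && length(cuff_ipsi) >= 2) {
      tt <- safe_t_test(sham_ipsi, cuff_ipsi)
      out[[length(out) + 1]] <- dplyr::bind_cols(st, tibble::tibble(
        comparison = "sham_vs_cuff_ipsi",
        estimate = mean(sham_ipsi) - mean(cuff_ipsi),
        statistic = tt$statistic, df = tt$df,
        p_value = tt$p, method = "Welch two-sample t-test"))
    } else {
      warning("skipping sham-vs-cuff comparison for a degenerate stratum (day ",
              st$day, ")", call. = FALSE)
    }
    # ipsi vs contra within cuff animals, paired
    wide <- cuff |>
      dplyr::select(animal, side, value) |>
      tidyr::pivot_wider(names_from = side, values_from = value)
    if (all(c("ipsilateral", "contralateral") %in% names(wide)) &&
        sum(stats::complete.cases(wide)) >= 2) {
      cc <- wide[stats::complete.cases(wide), ]
      tt <- safe_t_test(cc$ipsilateral, cc$contralateral, paired = TRUE)
      out[[length(out) + 1]] <- dplyr::bind_cols(st, tibble::tibble(
        comparison = "cuff_ipsi_vs_contra",
        estimate = mean(cc$ipsilateral - cc$contralateral),
        statistic = tt$statistic, df = tt$df,
        p_value = tt$p, method = "paired t-test"))
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(day = numeric(), comparison = character(),
                          estimate = numeric(), statistic = numeric(),
                          df = numeric(), p_value = numeric(),
                          method = character(), p_adjusted = numeric()))
  }
  # Bonferroni within comparison type across days, per endpoint
  res |>
    dplyr::group_by(comparison,
                    dplyr::across(dplyr::all_of(endpoint_cols))) |>
    dplyr::mutate(p_adjusted = pmin(1, p_value * dplyr::n())) |>
    dplyr::ungroup()
}

# t.test that degrades gracefully when the data are essentially constant
# (e.g. identical paired values): returns NA statistic and p-value.
safe_t_test <- function(x, y, paired = FALSE) {
  res <- tryCatch(stats::t.test(x, y, paired = paired),
                  error = function(e) NULL)
  if (is.null(res)) {
    list(statistic = NA_real_, df = NA_real_, p = NA_real_)
  } else {
    list(statistic = unname(res$statistic), df = unname(res$parameter),
         p = res$p.value)
  }
}

compare_behavior <- function(per_animal, endpoint_cols) {
  out <- list()
  strata <- per_animal |>
    dplyr::distinct(dplyr::across(dplyr::all_of(endpoint_cols)))
  for (i in seq_len(nrow(strata))) {
    st <- strata[i, ]
    d <- dplyr::semi_join(per_animal, st, by = names(st)) |>
      dplyr::filter(side == "ipsilateral")
    if (length(unique(d$day)) >= 2 && length(unique(d$group)) == 2) {
      fit <- stats::aov(value ~ group * factor(day), data = d)
      an <- summary(fit)[[1]]
      grp_row <- grep("^group", rownames(an))[1]
      out[[length(out) + 1]] <- dplyr::bind_cols(st, tibble::tibble(
        comparison = "anova_group_effect", day = NA_real_,
        estimate = NA_real_,
        statistic = an[grp_row, "F value"], df = an[grp_row, "Df"],
        p_value = an[grp_row, "Pr(>F)"],
        method = "two-way ANOVA (group x day)"))
    }
    days <- sort(unique(d$day))
    m <- length(days)
    for (dy in days) {
      dd <- d[d$day == dy, ]
      sham <- dd$value[dd$group == "sham"]
      cuff <- dd$value[dd$group == "cuff"]
      if (length(sham) >= 2 && length(cuff) >= 2) {
        tt <- stats::t.test(sham, cuff)
        out[[length(out) + 1]] <- dplyr::bind_cols(st, tibble::tibble(
          comparison = "sham_vs_cuff_ipsi", day = dy,
          estimate = mean(sham) - mean(cuff),
          statistic = unname(tt$statistic), df = unname(tt$parameter),
          p_value = tt$p.value,
          method = sprintf("per-day t-test, Bonferroni m=%d", m)))
      } else {
        warning("skipping day ", dy, ": fewer than two animals per group",
                call. = FALSE)
      }
    }
  }
  res <- dplyr::bind_rows(out)
  res$p_adjusted <- ifelse(res$comparison == "sham_vs_cuff_ipsi",
                           pmin(1, res$p_value *
                                  ave(res$p_value, res$comparison,
                                      FUN = length)),
                           res$p_value)
  res
}

#' Phase-wise Spearman correlation between IB4 and GAD65 densities
#'
#' Pools one (IB4 mean, GAD65 mean) density pair per animal per day across
#' the days of a phase (e.g. the decreasing phase, days 5-14, or the
#' recovery phase, days 21-56) and computes the Spearman rank correlation.
#' The p-value uses the exact null distribution for n <= 12 without ties
#' and the t approximation otherwise.
#'
#' @param per_animal_densities tibble with one row per animal x day x
#'   marker: columns `animal`, `day`, `marker`, `value` (use
#'   [animal_means()] output filtered to one lamina and side).
#' @param phase_days days belonging to the phase.
#' @param phase_label optional label stored with the result.
#' @return an object of class `dh_phase_cor`: one-row tibble with `phase`,
#'   `r` (Spearman rho), `p_value`, `n`, `method`.
#' @export
phase_correlation <- function(per_animal_densities, phase_days,
                              phase_label = paste(range(phase_days),
                                                  collapse = "-")) {
  stopifnot(all(c("animal", "day", "marker", "value") %in%
                  names(per_animal_densities)))
  d <- per_animal_densities |>
    dplyr::filter(day %in% phase_days) |>
    tidyr::pivot_wider(id_cols = c(animal, day), names_from = marker,
                       values_from = value)
  if (!all(c("IB4", "GAD65") %in% names(d))) {
    stop("need both IB4 and GAD65 values per animal", call. = FALSE)
  }
  d <- d[stats::complete.cases(d[, c("IB4", "GAD65")]), ]
  n <- nrow(d)
  if (n < 4) stop("fewer than 4 pairs; correlation is meaningless", call. = FALSE)
  x <- d$IB4; y <- d$GAD65
  rho <- stats::cor(x, y, method = "spearman")
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 12 && !ties) {
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = TRUE))
    p <- ct$p.value
    method <- "Spearman, exact null"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "Spearman, t approximation"
  }
  out <- tibble::tibble(phase = phase_label, r = rho, p_value = p,
                        n = n, method = method)
  class(out) <- c("dh_phase_cor", class(out))
  out
}

#' Full cohort analysis
#'
#' Composes the statistics stage: animal-level aggregation, percent-of-sham
#' normalisation, group comparisons on absolute values, and the two-phase
#' IB4-GAD65 Spearman correlations over lamina-II ipsilateral densities.
#'
#' @param density_records section-level density records (from
#'   [quantify_dataset()] or [simulate_quantify_day()]), any number of days.
#' @param behavior_scores optional per-animal behavioural endpoints
#'   ([score_behavior()] output with a `day` column).
#' @param decreasing_days,recovery_days day sets of the two phases.
#' @return list with `normalized` (histology and, if given, behaviour),
#'   `comparisons`, `correlations` (a two-row tibble when both phases have
#'   at least 4 pairs), and `per_animal`.
#' @export
analyze_cohort <- function(density_records, behavior_scores = NULL,
                           decreasing_days = c(5, 7, 10, 14),
                           recovery_days = c(21, 28, 42, 56)) {
  per_animal <- animal_means(density_records)
  normalized <- normalize_to_sham(per_animal,
                                  endpoint_cols = c("lamina", "marker"))
  comparisons <- compare_groups(per_animal, design = "histology")

  lii_ipsi <- per_animal |>
    dplyr::filter(lamina == "LII", side == "ipsilateral", group == "cuff") |>
    dplyr::select(animal, day, marker, value)
  correlations <- list()
  for (ph in list(list(days = decreasing_days, label = "decreasing"),
                  list(days = recovery_days, label = "recovery"))) {
    sub <- lii_ipsi[lii_ipsi$day %in% ph$days, ]
    if (length(unique(paste(sub$animal, sub$day))) >= 4 &&
        all(c("IB4", "GAD65") %in% sub$marker)) {
      correlations[[ph$label]] <-
        phase_correlation(lii_ipsi, ph$days, ph$label)
    }
  }
  correlations <- dplyr::bind_rows(correlations)
  if (nrow(correlations)) {
    class(correlations) <- c("dh_phase_cor", class(correlations))
  }
  out <- list(per_animal = per_animal,
              normalized = normalized,
              comparisons = comparisons,
              correlations = correlations)

  if (!is.null(behavior_scores)) {
    beh <- behavior_scores
    out$behavior_normalized <- normalize_to_sham(beh, endpoint_cols = "endpoint")
    out$behavior_comparisons <- compare_groups(beh, design = "behavior",
                                               endpoint_cols = "endpoint")
  }
  out
}
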
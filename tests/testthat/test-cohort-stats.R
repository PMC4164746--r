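make_animals <- function(sham, cuff, day = 21, lamina = "LII",
                         marker = "IB4", side = "ipsilateral") {
  tibble::tibble(
    animal = c(sprintf("sham_%02d", seq_along(sham)),
               sprintf("cuff_%02d", seq_along(cuff))),
    group = rep(c("sham", "cuff"), c(length(sham), length(cuff))),
    day = day, side = side, lamina = lamina, marker = marker,
    value = c(sham, cuff))
}

test_that("percent-of-sham normalisation matches hand arithmetic", {
  d <- make_animals(sham = c(12, 12, 12), cuff = c(3, 3))
  norm <- normalize_to_sham(d)
  cuff <- norm[norm$group == "cuff", ]
  sham <- norm[norm$group == "sham", ]
  expect_equal(cuff$mean_pct_of_sham, 25)
  expect_equal(sham$mean_pct_of_sham, 100)  # sham is 100% by construction
  expect_equal(cuff$n_animals, 2)

  same <- make_animals(sham = c(10, 14), cuff = c(12, 12))
  expect_equal(normalize_to_sham(same)[2, ]$mean_pct_of_sham, 100)

  no_sham <- make_animals(sham = numeric(), cuff = c(3, 3))
  expect_error(normalize_to_sham(no_sham), "day=21")
})

test_that("identical groups are never declared different", {
  set.seed(5)
  vals <- rnorm(6, 10, 1)
  d <- dplyr::bind_rows(
    make_animals(sham = vals, cuff = vals),
    dplyr::mutate(make_animals(sham = vals, cuff = vals),
                  side = "contralateral"))
  cmp <- compare_groups(d, design = "histology")
  expect_true(all(!cmp$significant))
  sham_cuff <- cmp[cmp$comparison == "sham_vs_cuff_ipsi", ]
  expect_true(all(sham_cuff$p_adjusted > 0.9))
})

test_that("a strong reduction is detected with high power", {
  hits <- vapply(1:200, function(s) {
    set.seed(s)
    d <- make_animals(sham = rnorm(6, 10, 2), cuff = rnorm(6, 2, 0.4))
    cmp <- compare_groups(d, design = "histology")
    cmp$significant[cmp$comparison == "sham_vs_cuff_ipsi"]
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("Bonferroni adjustment is min(1, m * p) across days", {
  set.seed(9)
  days <- c(5, 14, 21)
  d <- dplyr::bind_rows(lapply(days, function(dy)
    tibble::tibble(animal = sprintf("a%02d", 1:12),
                   group = rep(c("sham", "cuff"), each = 6),
                   day = dy, side = "ipsilateral", endpoint = "von_frey",
                   value = rnorm(12, 10, 2))))
  cmp <- compare_groups(d, design = "behavior", endpoint_cols = "endpoint")
  perday <- cmp[cmp$comparison == "sham_vs_cuff_ipsi", ]
  expect_equal(perday$p_adjusted, pmin(1, perday$p_value * length(days)))
  expect_true("anova_group_effect" %in% cmp$comparison)
})

test_that("Spearman correlation handles perfect and inverse rankings", {
  mono <- tibble::tibble(animal = rep(sprintf("a%d", 1:6), 2), day = 5,
                         marker = rep(c("IB4", "GAD65"), each = 6),
                         value = c(1:6, (1:6)^3))
  r <- phase_correlation(mono, 5)
  expect_equal(r$r, 1)

  inv <- tibble::tibble(animal = rep(sprintf("a%d", 1:4), 2), day = 5,
                        marker = rep(c("IB4", "GAD65"), each = 4),
                        value = c(1, 2, 3, 4, 4, 3, 2, 1))
  expect_equal(phase_correlation(inv, 5)$r, -1)

  few <- inv[c(1, 2, 5, 6), ]
  expect_error(phase_correlation(few, 5), "fewer than 4")
})

test_that("Spearman rho is invariant under monotone transforms and p-values match cor.test", {
  set.seed(21)
  x <- rnorm(10); y <- rnorm(10)
  base <- tibble::tibble(animal = rep(sprintf("a%d", 1:10), 2), day = 7,
                         marker = rep(c("IB4", "GAD65"), each = 10),
                         value = c(x, y))
  warped <- base
  warped$value[1:10] <- exp(x)          # strictly monotone transform of IB4
  r1 <- phase_correlation(base, 7)
  r2 <- phase_correlation(warped, 7)
  expect_equal(r1$r, r2$r)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = TRUE))
  expect_equal(r1$p_value, ct$p.value)
  expect_match(r1$method, "exact")
  # large-n path uses the t approximation
  set.seed(22)
  big <- tibble::tibble(animal = rep(sprintf("a%d", 1:25), 2), day = 7,
                        marker = rep(c("IB4", "GAD65"), each = 25),
                        value = rnorm(50))
  expect_match(phase_correlation(big, 7)$method, "t approximation")
})

test_that("analyze_cohort wires aggregation, normalisation and correlations", {
  set.seed(33)
  days <- c(5, 7, 10, 14)
  recs <- dplyr::bind_rows(lapply(days, function(dy) {
    dplyr::bind_rows(lapply(c("sham", "cuff"), function(g) {
      n <- 5
      tidyr::expand_grid(animal = sprintf("%s_%02d_%d", g, 1:n, dy),
                         section = 1:2,
                         side = c("ipsilateral", "contralateral"),
                         lamina = c("LI", "LII"),
                         marker = c("IB4", "GAD65")) |>
        dplyr::mutate(group = g, day = dy,
                      density = rlnorm(dplyr::n(), log(10), 0.2) *
                        ifelse(g == "cuff" & side == "ipsilateral", 0.5, 1))
    }))
  }))
  res <- analyze_cohort(recs, decreasing_days = days, recovery_days = c(21))
  expect_s3_class(res$normalized, "dh_normalized")
  sham_rows <- res$normalized[res$normalized$group == "sham", ]
  expect_true(all(abs(sham_rows$mean_pct_of_sham - 100) < 1e-9))
  expect_equal(nrow(res$correlations), 1)
  expect_equal(res$correlations$n, 5 * length(days))
  td <- tidy(res$correlations)
  expect_true(all(c("estimate", "p.value") %in% names(td)))
})
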
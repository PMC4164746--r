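#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a phase-correlation result
#'
#' @param x a [phase_correlation()] result.
#' @param ... unused.
#' @return a tibble with `phase`, `estimate`, `p.value`, `n`, `method`.
#' @method tidy dh_phase_cor
#' @export
tidy.dh_phase_cor <- function(x, ...) {
  tibble::tibble(phase = x$phase, estimate = x$r, p.value = x$p_value,
                 n = x$n, method = x$method)
}

#' @rdname tidy.dh_phase_cor
#' @method glance dh_phase_cor
#' @export
glance.dh_phase_cor <- function(x, ...) tidy.dh_phase_cor(x, ...)

#' Tidy group-comparison results
#'
#' @param x a [compare_groups()] result.
#' @param ... unused.
#' @return a tibble with one row per test: `comparison`, `day`, endpoint
#'   identifiers, `estimate`, `statistic`, `p.value`, `p.adjusted`.
#' @method tidy dh_comparisons
#' @export
tidy.dh_comparisons <- function(x, ...) {
  out <- tibble::as_tibble(x)
  names(out)[names(out) == "p_value"] <- "p.value"
  names(out)[names(out) == "p_adjusted"] <- "p.adjusted"
  out
}

#' Tidy an up-down threshold estimate
#'
#' @param x an [estimate_threshold()] result.
#' @param ... unused.
#' @return one-row tibble with `estimate` (grams), `x.f`, `k`, `delta`,
#'   `censored`, `n.trials`.
#' @method tidy dh_threshold
#' @export
tidy.dh_threshold <- function(x, ...) {
  tibble::tibble(estimate = x$threshold_g, x.f = x$x_f, k = x$k,
                 delta = x$delta, censored = x$censored,
                 n.trials = x$n_trials)
}
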
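#' Dixon k value for an up-down response pattern
#'
#' The up-down 50% threshold formula `(10^[Xf + k*delta]) / 10000` needs the
#' pattern value k for the observed sequence of withdrawals ("X") and
#' non-withdrawals ("0"). k is obtained here by the construction that
#' defines Dixon's published tables: the maximum-likelihood location of a
#' cumulative-normal psychometric function with spread equal to the stimulus
#' spacing `delta` (in log10 units of 10000 x grams), expressed as an offset
#' from the final stimulus in units of `delta`:
#' `k = (mu_ML - Xf) / delta`.
#'
#' @param filament_g filament forces presented, in grams.
#' @param response character vector of `"X"` / `"0"` per presentation.
#' @param delta mean log-unit stimulus spacing (0.224 for this filament
#'   set).
#' @return the scalar k.
#' @seealso [estimate_threshold()]
#' @export
dixon_k <- function(filament_g, response, delta = 0.224) {
  stopifnot(length(filament_g) == length(response),
            all(response %in% c("X", "0")))
  x <- log10(10000 * filament_g)
  y <- as.numeric(response == "X")
  if (all(y == 1) || all(y == 0)) {
    stop("one-sided response pattern has no finite ML location; censor instead",
         call. = FALSE)
  }
  negll <- function(mu) {
    p <- stats::pnorm((x - mu) / delta)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(y * log(p) + (1 - y) * log(1 - p))
  }
  span <- range(x)
  opt <- stats::optimize(negll, interval = c(span[1] - 4 * delta,
                                             span[2] + 4 * delta))
  xf <- x[length(x)]
  (opt$minimum - xf) / delta
}

#' Up-down 50% withdrawal threshold from a von Frey sequence
#'
#' Scores a staircase with the Dixon up-down formula
#' `threshold = (10^[Xf + k*delta]) / 10000` grams, where `Xf` is the final
#' filament's value in log10 units of 10000 x grams, `delta = 0.224` is the
#' mean log spacing of the filament set, and `k` is the pattern value
#' ([dixon_k()]). Sequences with no withdrawal at all are censored at the
#' strongest filament; sequences with no non-withdrawal are censored at the
#' weakest.
#'
#' @param seq a [simulate_updown_trials()] object, or any tibble with
#'   columns `filament_g` and `response` (`"X"`/`"0"`) and a `filament_set`
#'   attribute (defaults to the study's 0.6-26 g set).
#' @param delta mean log-unit stimulus spacing.
#' @param validate check the up-down transition rule and fail on the first
#'   violating step.
#' @return an object of class `dh_threshold`: a one-row tibble with
#'   `threshold_g`, `x_f`, `k`, `delta`, `censored`
#'   (`"none"`/`"high"`/`"low"`) and `n_trials`.
#' @examples
#' s <- simulate_updown_trials(4, 5, seed = 1)
#' estimate_threshold(s)
#' @export
estimate_threshold <- function(seq, delta = 0.224, validate = TRUE) {
  stopifnot(all(c("filament_g", "response") %in% names(seq)))
  if (nrow(seq) < 1) stop("empty sequence", call. = FALSE)
  fils <- attr(seq, "filament_set") %||% c(0.6, 1, 1.4, 2, 4, 6, 8, 10, 15, 26)
  f <- seq$filament_g
  resp <- seq$response
  if (!all(resp %in% c("X", "0"))) {
    stop("responses must be 'X' (withdrawal) or '0' (none)", call. = FALSE)
  }
  if (validate && nrow(seq) > 1) {
    idx <- match(f, fils)
    if (anyNA(idx)) stop("presentation uses a filament outside the set", call. = FALSE)
    for (i in seq_len(length(f) - 1)) {
      expected <- if (resp[i] == "X") max(idx[i] - 1L, 1L) else
        min(idx[i] + 1L, length(fils))
      if (idx[i + 1] != expected) {
        stop(sprintf(
          "up-down rule violated at step %d: %s at %g g must be followed by %g g, got %g g",
          i, resp[i], f[i], fils[expected], f[i + 1]), call. = FALSE)
      }
    }
  }

  res <- function(threshold, x_f, k, censored) {
    out <- tibble::tibble(threshold_g = threshold, x_f = x_f, k = k,
                          delta = delta, censored = censored,
                          n_trials = nrow(seq))
    class(out) <- c("dh_threshold", class(out))
    out
  }
  if (!any(resp == "X")) {
    return(res(max(fils), log10(10000 * max(fils)), NA_real_, "high"))
  }
  if (!any(resp == "0")) {
    return(res(min(fils), log10(10000 * min(fils)), NA_real_, "low"))
  }
  x_f <- log10(10000 * f[length(f)])
  k <- dixon_k(f, resp, delta)
  thr <- (10^(x_f + k * delta)) / 10000
  res(thr, x_f, k, "none")
}

#' Hargreaves withdrawal latency from trial measurements
#'
#' The reported latency is the arithmetic mean of the (up to three) trial
#' latencies, each of which must respect the apparatus cut-off.
#'
#' @param trials numeric vector of 1-3 trial latencies in seconds.
#' @param cutoff_s apparatus cut-off in seconds.
#' @return mean latency in seconds.
#' @examples
#' hargreaves_latency(c(9, 10, 11))
#' @export
hargreaves_latency <- function(trials, cutoff_s = 20.48) {
  stopifnot(length(trials) >= 1, length(trials) <= 3)
  if (any(trials > cutoff_s + 1e-9)) {
    stop("trial latency exceeds the cut-off; trials must be clipped at acquisition",
         call. = FALSE)
  }
  if (any(trials <= 0)) stop("latencies must be positive", call. = FALSE)
  mean(trials)
}

#' Score a simulated behavioural cohort
#'
#' Applies the up-down threshold estimator to every von Frey sequence and
#' the trial average to every Hargreaves animal, returning one endpoint row
#' per animal x side.
#'
#' @param behavior list from [simulate_behavior_cohort()].
#' @param delta log spacing for the up-down formula.
#' @param cutoff_s Hargreaves cut-off.
#' @return tibble with columns `animal`, `group`, `side`, `endpoint`,
#'   `value` (grams for `von_frey`, seconds for `hargreaves`), `censored`.
#' @export
score_behavior <- function(behavior, delta = 0.224, cutoff_s = 20.48) {
  vf <- behavior$vf_trials |>
    dplyr::group_by(animal, group, side) |>
    dplyr::group_modify(function(d, key) {
      r <- estimate_threshold(d, delta = delta)
      tibble::tibble(endpoint = "von_frey", value = r$threshold_g,
                     censored = r$censored)
    }) |>
    dplyr::ungroup()
  hg <- behavior$hg_trials |>
    dplyr::group_by(animal, group, side) |>
    dplyr::summarise(endpoint = "hargreaves",
                     value = hargreaves_latency(latency_s, cutoff_s),
                     censored = "none", .groups = "drop")
  dplyr::bind_rows(vf, hg)
}
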
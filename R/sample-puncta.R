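#' Sample a homogeneous Poisson field of puncta within a region
#'
#' Draws synaptic-bouton ground truth for one channel: punctum centres follow
#' a homogeneous spatial Poisson process over the region at the requested
#' density, and single-punctum (apparent) areas follow a log-normal
#' distribution with the requested mean and coefficient of variation. Density
#' uses the study's reporting unit, puncta per 100 square microns.
#'
#' The region may be a named rectangle `(x0, x1, y0, y1)` in microns, or a
#' rectangle plus a membership predicate for non-rectangular regions (the
#' rectangle is then the bounding box used for Poisson sampling and the
#' predicate thins points outside the region; the density applies to the
#' accepted region's true area, which must be supplied).
#'
#' @param region named numeric rectangle (x0, x1, y0, y1) in microns.
#' @param density expected puncta per 100 square microns; must be `>= 0`.
#' @param mean_area mean single-punctum area in square microns (0.3 for IB4
#'   terminals, 0.2 for GAD65 boutons).
#' @param area_cv coefficient of variation of punctum area (log-normal).
#' @param channel channel label stored with every punctum.
#' @param amp_range punctum peak amplitudes (DN above background) are drawn
#'   uniformly from this band; see [noise_model()].
#' @param seed integer seed; identical arguments and seed give an identical
#'   field.
#' @return an object of class `dh_puncta`: a tibble with columns `x_um`,
#'   `y_um`, `area_um2`, `amplitude`, `channel`, and attributes `region`,
#'   `true_density` (per 100 um^2) and `mean_area`.
#' @examples
#' f <- sample_puncta(c(x0 = 0, x1 = 30, y0 = 0, y1 = 50), density = 20,
#'                    mean_area = 0.3, seed = 1)
#' nrow(f)  # ~ Poisson(20 * 15)
#' @export
sample_puncta <- function(region, density, mean_area, area_cv = 0.5,
                          channel = "IB4", amp_range = c(400, 1200),
                          seed = 1L) {
  if (density < 0) stop("density must be non-negative", call. = FALSE)
  stopifnot(mean_area > 0, area_cv >= 0)
  region <- region[c("x0", "x1", "y0", "y1")]
  area_um2 <- rect_area(region)
  stopifnot(area_um2 > 0)

  withr_seed(seed, {
    n <- stats::rpois(1, density * area_um2 / 100)
    x <- stats::runif(n, region[["x0"]], region[["x1"]])
    y <- stats::runif(n, region[["y0"]], region[["y1"]])
    a <- rlnorm_mean_cv(n, mean_area, area_cv)
    amp <- stats::runif(n, amp_range[1], amp_range[2])
  })

  out <- tibble::tibble(
    x_um = x, y_um = y, area_um2 = a, amplitude = amp,
    channel = rep(channel, n)
  )
  attr(out, "region") <- region
  attr(out, "true_density") <- density
  attr(out, "mean_area") <- mean_area
  class(out) <- c("dh_puncta", class(out))
  out
}

#' Log-normal deviates parameterised by mean and CV
#'
#' @param n number of draws.
#' @param mean arithmetic mean of the distribution.
#' @param cv coefficient of variation; `cv = 0` returns the constant mean.
#' @return numeric vector of positive deviates.
#' @keywords internal
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}

# Evaluate `code` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so package functions never disturb the session RNG.
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(code))
}

# Deterministic sub-seed derivation: mixes a base seed with stream indices
# into a 31-bit integer, so cohort components get independent, reproducible
# streams (seed, animal, section, channel, ...).
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed %% 2147483647)
  for (k in idx) {
    s <- (s * 69069 + as.double(k) * 2654435761 + 12345) %% 2147483647
  }
  as.integer(s %% 2147483646) + 1L
}
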
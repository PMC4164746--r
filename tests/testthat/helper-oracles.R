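# Independent oracles and small fixtures used across the suite.

# Brute-force 4-connected component count by flood fill, independent of the
# package's segmentation path. Returns component pixel sizes.
flood_sizes <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  sizes <- integer(0)
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- matrix(c(i, j), ncol = 2)
    lab[i, j] <- cur
    size <- 0L
    while (nrow(queue) > 0) {
      p <- queue[1, , drop = FALSE]
      queue <- queue[-1, , drop = FALSE]
      size <- size + 1L
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ni <- p[1] + d[1]; nj <- p[2] + d[2]
        if (ni >= 1 && ni <= nr && nj >= 1 && nj <= nc &&
            mask[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- cur
          queue <- rbind(queue, c(ni, nj))
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sizes
}

# Maximum-likelihood threshold for one up-down sequence under the true
# logistic psychometric model (slope known), independent of the Dixon
# formula path.
ml_logistic_threshold <- function(filament_g, response, slope = 5) {
  x <- log10(filament_g)
  y <- as.numeric(response == "X")
  negll <- function(lt) {
    p <- stats::plogis(slope * (x - lt))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(y * log(p) + (1 - y) * log(1 - p))
  }
  opt <- stats::optimize(negll, interval = c(log10(0.6) - 1, log10(26) + 1))
  10^opt$minimum
}

# Small section geometry that keeps renders fast while fitting both ROIs
# and a middle-third lesion zone.
test_geometry <- function(width_um = 420, height_um = 150,
                          lesion_width_um = 60, ...) {
  generate_geometry(width_um = width_um, height_um = height_um,
                    lesion_width_um = lesion_width_um, ...)
}

# Draw n well-separated discs of a given area on a grid; returns the puncta
# tibble understood by render_micrograph().
grid_puncta <- function(n, area_um2, region, spacing_um = 4,
                        amplitude = 1000, channel = "IB4") {
  per_row <- floor((region[["x1"]] - region[["x0"]]) / spacing_um)
  stopifnot(per_row >= 1)
  ix <- (seq_len(n) - 1) %% per_row
  iy <- (seq_len(n) - 1) %/% per_row
  # offset by half a pixel (0.05 um at the default scale) so disc centres sit
  # on pixel centres and quantisation is deterministic and near-unbiased
  out <- tibble::tibble(
    x_um = region[["x0"]] + spacing_um / 2 + 0.05 + ix * spacing_um,
    y_um = region[["y0"]] + spacing_um / 2 + 0.05 + iy * spacing_um,
    area_um2 = rep(area_um2, n),
    amplitude = rep(amplitude, n),
    channel = rep(channel, n)
  )
  stopifnot(all(out$y_um < region[["y1"]]))
  out
}
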
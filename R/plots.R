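#' Plot a percent-of-sham time-course
#'
#' The study's standard reporting panel: mean +/- SEM percent of sham per
#' day for each group/side, one facet per endpoint stratum.
#'
#' @param normalized a [normalize_to_sham()] result with a `day` column.
#' @param facets faceting columns (defaults to whatever of
#'   `lamina`/`marker`/`endpoint` is present).
#' @return a ggplot object.
#' @export
plot_timecourse <- function(normalized, facets = NULL) {
  stopifnot("day" %in% names(normalized))
  if (is.null(facets)) {
    facets <- intersect(c("lamina", "marker", "endpoint"), names(normalized))
  }
  d <- dplyr::mutate(normalized,
                     series = paste(group, side, sep = " / "))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = day, y = mean_pct_of_sham,
                                       colour = series, group = series)) +
    ggplot2::geom_hline(yintercept = 100, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = mean_pct_of_sham - sem_pct,
      ymax = mean_pct_of_sham + sem_pct)) +
    ggplot2::labs(x = "days post-surgery", y = "% of sham (mean ± SEM)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (length(facets)) {
    p <- p + ggplot2::facet_wrap(facets, scales = "free_y")
  }
  p
}

#' @rdname plot_timecourse
#' @param object a `dh_normalized` object.
#' @param ... passed to [plot_timecourse()].
#' @method autoplot dh_normalized
#' @export
autoplot.dh_normalized <- function(object, ...) plot_timecourse(object, ...)

#' Display a micrograph channel with ROIs overlaid
#'
#' Quick-look rendering of one channel (downsampled for display) with the
#' placed quantification rectangles.
#'
#' @param micrograph a [render_micrograph()] object.
#' @param channel channel name.
#' @param rois optional [place_rois()] tibble to overlay.
#' @param downsample integer pixel stride for display.
#' @return a ggplot object.
#' @export
plot_micrograph <- function(micrograph, channel = names(micrograph$channels)[1],
                            rois = NULL, downsample = 4L) {
  ch <- micrograph$channels[[channel]]
  px <- micrograph$pixel_size_um
  ii <- seq(1, nrow(ch), by = downsample)
  jj <- seq(1, ncol(ch), by = downsample)
  d <- expand.grid(y_um = (ii - 0.5) * px, x_um = (jj - 0.5) * px)
  d$dn <- as.vector(ch[ii, jj])
  p <- ggplot2::ggplot(d, ggplot2::aes(x_um, y_um, fill = dn)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", fill = "DN",
                  title = channel) +
    ggplot2::theme_minimal()
  if (!is.null(rois)) {
    p <- p + ggplot2::geom_rect(
      data = as.data.frame(rois),
      ggplot2::aes(xmin = x0, xmax = x1, ymin = y0, ymax = y1),
      inherit.aes = FALSE, colour = "yellow", fill = NA)
  }
  p
}
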
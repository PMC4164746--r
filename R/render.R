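#' Render puncta fields into a two-channel 12-bit micrograph
#'
#' Rasterises per-channel ground-truth puncta fields onto the section's pixel
#' grid. Each punctum is drawn as a uniform disc of its configured apparent
#' area at its peak amplitude (amplitudes of overlapping puncta add, as
#' fluorescence does), the channel is optionally blurred with a Gaussian PSF,
#' background offset and Gaussian read noise are added, and the result is
#' quantised and clipped to the 12-bit range.
#'
#' @param geometry a [generate_geometry()] object defining the pixel grid.
#' @param fields named list of [sample_puncta()] fields, one per channel
#'   (e.g. `list(IB4 = ..., GAD65 = ...)`). A channel may be an empty field.
#' @param noise a [noise_model()] object.
#' @param seed integer seed controlling the noise realisation.
#' @return an object of class `dh_micrograph`: a list with `channels` (named
#'   list of integer matrices, DN), `pixel_size_um`, `noise`, and `geometry`.
#' @examples
#' geom <- generate_geometry(width_um = 320, height_um = 160, seed = 1)
#' f <- sample_puncta(c(x0 = 10, x1 = 60, y0 = 40, y1 = 90), 10, 0.3, seed = 2)
#' mg <- render_micrograph(geom, list(IB4 = f), noise_model(), seed = 3)
#' range(mg$channels$IB4)
#' @export
render_micrograph <- function(geometry, fields, noise = noise_model(), seed = 1L) {
  stopifnot(inherits(geometry, "dh_geometry"), inherits(noise, "dh_noise"))
  if (is.null(names(fields)) || any(names(fields) == "")) {
    stop("`fields` must be a named list of puncta fields (one per channel)",
         call. = FALSE)
  }
  nr <- geometry$image_shape[["rows"]]
  nc <- geometry$image_shape[["cols"]]
  px <- geometry$pixel_size_um
  max_dn <- 2^noise$bit_depth - 1

  channels <- vector("list", length(fields))
  names(channels) <- names(fields)
  for (k in seq_along(fields)) {
    ch_seed <- derive_seed(seed, 7L, k)
    signal <- rasterize_puncta(fields[[k]], nr, nc, px)
    if (noise$psf_sigma_um > 0) {
      signal <- EBImage::gblur(signal, sigma = noise$psf_sigma_um / px)
      signal[signal < 0] <- 0
    }
    channels[[k]] <- withr_seed(ch_seed,
      .finalize_channel(signal, noise$background_level, noise$background_sd,
                        noise$photon_noise, max_dn))
  }

  structure(
    list(channels = channels,
         pixel_size_um = px,
         noise = noise,
         geometry = geometry),
    class = "dh_micrograph"
  )
}

#' @export
print.dh_micrograph <- function(x, ...) {
  cat("<dh_micrograph> ", paste(names(x$channels), collapse = " + "),
      ", ", nrow(x$channels[[1]]), " x ", ncol(x$channels[[1]]), " px @ ",
      x$pixel_size_um, " um/px\n", sep = "")
  invisible(x)
}

# Draw puncta as uniform discs on a zero matrix (DN above background).
# Pixel (i, j) has centre ((j - 0.5) px, (i - 0.5) px). A pixel belongs to a
# punctum if its centre lies within the punctum's disc; for sub-pixel discs
# the nearest pixel is used so no punctum vanishes. The inner loop is
# compiled (src/morphology.cpp).
rasterize_puncta <- function(field, nr, nc, px) {
  if (is.null(field) || nrow(field) == 0) return(matrix(0, nr, nc))
  cx <- field$x_um / px   # pixel units
  cy <- field$y_um / px
  r <- sqrt(field$area_um2 / pi) / px
  amp <- field$amplitude
  if (any(cx < 0 | cx > nc | cy < 0 | cy > nr)) {
    warning("punctum centre outside the image; clipped to the frame",
            call. = FALSE)
  }
  .rasterize_discs(cx, cy, r, amp, nr, nc)
}
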
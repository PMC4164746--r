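#' Imaging noise model for rendered micrographs
#'
#' Parameters of the camera/detector model applied when rasterising a puncta
#' field into a 12-bit micrograph: a constant background offset with Gaussian
#' read noise, optional Poisson photon noise, and an optional Gaussian PSF.
#'
#' Intensities are digital numbers (DN) on a 12-bit scale; rendered images
#' are clipped to `[0, 4095]`. The default PSF sigma is 0: the configured
#' mean puncta areas are the *apparent* areas measured through the
#' microscope, so puncta are rasterised at exactly those areas and further
#' blur is opt-in (e.g. to study defocus sensitivity).
#'
#' @param background_level mean background in DN.
#' @param background_sd Gaussian read-noise standard deviation in DN.
#' @param psf_sigma_um Gaussian PSF sigma in microns (0 = no blur).
#' @param photon_noise logical; if `TRUE`, pixel values are Poisson-resampled
#'   around their noiseless mean before read noise is added.
#' @param amp_range two DN values; punctum peak amplitudes (above background)
#'   are drawn uniformly from this band. The default keeps peaks well below
#'   the 12-bit ceiling so puncta never saturate.
#' @param bit_depth image bit depth; fixed at 12 for this study design.
#' @return an object of class `dh_noise` (a named list).
#' @examples
#' noise_model()
#' @export
noise_model <- function(background_level = 100,
                        background_sd = 10,
                        psf_sigma_um = 0,
                        photon_noise = FALSE,
                        amp_range = c(400, 1200),
                        bit_depth = 12L) {
  stopifnot(background_level >= 0, background_sd >= 0, psf_sigma_um >= 0,
            length(amp_range) == 2, amp_range[1] > 0, amp_range[2] >= amp_range[1],
            bit_depth == 12L)
  if (background_level + amp_range[2] >= 2^bit_depth) {
    stop("punctum peaks would saturate the 12-bit range; lower amp_range or background",
         call. = FALSE)
  }
  structure(
    list(background_level = background_level,
         background_sd = background_sd,
         psf_sigma_um = psf_sigma_um,
         photon_noise = isTRUE(photon_noise),
         amp_range = amp_range,
         bit_depth = as.integer(bit_depth)),
    class = "dh_noise"
  )
}

#' @export
print.dh_noise <- function(x, ...) {
  cat("<dh_noise> background ", x$background_level, " +/- ", x$background_sd,
      " DN, PSF sigma ", x$psf_sigma_um, " um, peaks U(",
      x$amp_range[1], ", ", x$amp_range[2], ") DN, ",
      x$bit_depth, "-bit\n", sep = "")
  invisible(x)
}
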
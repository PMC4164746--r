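#' Write a micrograph as a multi-page TIFF with a YAML sidecar
#'
#' One TIFF page per channel; the 12-bit data are stored losslessly in a
#' 16-bit container (DN value = stored 16-bit integer). The sidecar
#' (`<image>.yaml`) records the channel names, pixel size, noise settings
#' and the section geometry parameters, so the image can be quantified
#' without any in-memory state.
#'
#' @param micrograph a [render_micrograph()] object.
#' @param path output TIFF path.
#' @return (invisibly) the sidecar path.
#' @export
write_micrograph <- function(micrograph, path) {
  stopifnot(inherits(micrograph, "dh_micrograph"))
  pages <- lapply(micrograph$channels, function(ch) ch / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  sidecar <- paste0(path, ".yaml")
  yaml::write_yaml(list(
    channels = as.list(names(micrograph$channels)),
    pixel_size_um = micrograph$pixel_size_um,
    bit_depth = micrograph$noise$bit_depth,
    noise = list(background_level = micrograph$noise$background_level,
                 background_sd = micrograph$noise$background_sd,
                 psf_sigma_um = micrograph$noise$psf_sigma_um),
    geometry = geometry_params(micrograph$geometry)
  ), sidecar)
  invisible(sidecar)
}

#' Read a micrograph written by [write_micrograph()]
#'
#' Also accepts any multi-page 16-bit TIFF accompanied by a YAML sidecar
#' with at least `channels`, `pixel_size_um` and `geometry` entries.
#'
#' @param path TIFF path; the sidecar is expected at `<path>.yaml`.
#' @return a `dh_micrograph` object.
#' @export
read_micrograph <- function(path) {
  sidecar <- paste0(path, ".yaml")
  if (!file.exists(sidecar)) {
    stop("missing sidecar: ", sidecar, call. = FALSE)
  }
  meta <- yaml::read_yaml(sidecar)
  pages <- tiff::readTIFF(path, all = TRUE)
  channels <- lapply(pages, function(p) {
    m <- round(p * 65535)
    storage.mode(m) <- "integer"
    m
  })
  names(channels) <- unlist(meta$channels)
  geometry <- do.call(generate_geometry, meta$geometry)
  noise <- noise_model(background_level = meta$noise$background_level %||% 100,
                       background_sd = meta$noise$background_sd %||% 10,
                       psf_sigma_um = meta$noise$psf_sigma_um %||% 0)
  structure(list(channels = channels,
                 pixel_size_um = meta$pixel_size_um,
                 noise = noise,
                 geometry = geometry),
            class = "dh_micrograph")
}

# geometry parameters sufficient to rebuild the object
geometry_params <- function(geometry) {
  lesion_w <- geometry$lesion_zone[["x1"]] - geometry$lesion_zone[["x0"]]
  third_c <- geometry$midline_x_um / 2  # centre of middle third of ipsi side
  lesion_c <- (geometry$lesion_zone[["x0"]] + geometry$lesion_zone[["x1"]]) / 2
  list(width_um = geometry$width_um,
       height_um = geometry$height_um,
       pixel_size_um = geometry$pixel_size_um,
       wm_y_um = geometry$wm_y_um,
       wm_curve_amp_um = geometry$wm_curve_amp_um,
       li_band_thickness_um = geometry$li_band_thickness_um,
       lii_band_thickness_um = geometry$lii_band_thickness_um,
       lesion_width_um = lesion_w,
       lesion_offset_um = lesion_c - third_c,
       seed = geometry$seed)
}

#' Write / read a run configuration as YAML
#'
#' @param config a named list (serialisable values only).
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns the list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

#' Quantify every image of a simulated (or sidecar-annotated) dataset
#'
#' Walks the dataset's manifest, reads each image with its sidecar, runs
#' [quantify_section()] and returns one density record per
#' section x side x lamina x marker. Images without a sidecar are skipped
#' with a warning.
#'
#' @param dataset_dir directory written by [simulate_cohort()] (must
#'   contain `manifest.csv`).
#' @param params a [quant_params()] list.
#' @param progress print one line per image.
#' @return tidy tibble of density records with animal/day/group metadata
#'   and, where the manifest provides it, the ground truth joined in.
#' @export
quantify_dataset <- function(dataset_dir, params = quant_params(),
                             progress = FALSE) {
  manifest_path <- file.path(dataset_dir, "manifest.csv")
  if (!file.exists(manifest_path)) {
    stop("no manifest.csv in ", dataset_dir, call. = FALSE)
  }
  manifest <- tibble::as_tibble(utils::read.csv(manifest_path))
  images <- unique(manifest$image)
  out <- list()
  for (img in images) {
    path <- file.path(dataset_dir, img)
    if (!file.exists(paste0(path, ".yaml"))) {
      warning("skipping image without sidecar: ", img, call. = FALSE)
      next
    }
    if (progress) message("quantifying ", img)
    mg <- read_micrograph(path)
    rec <- quantify_section(mg, params = params)
    meta <- manifest[manifest$image == img, ,
                     drop = FALSE][1, c("animal", "group", "day", "section")]
    rec <- dplyr::bind_cols(rec, meta[rep(1, nrow(rec)), ])
    truth <- manifest[manifest$image == img,
                      c("side", "lamina", "marker", "true_density", "true_count")]
    rec <- dplyr::left_join(rec, truth, by = c("side", "lamina", "marker"))
    out[[length(out) + 1]] <- rec
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(side = character(), lamina = character(),
                          marker = character(), raw_blob_count = integer(),
                          corrected_count = numeric(), roi_area_um2 = numeric(),
                          density = numeric(), placement_mode = character(),
                          animal = character(), group = character(),
                          day = numeric(), section = integer())
  }
  res$schema_version <- 1L
  res
}
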
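#' Detect the lesion zone from windowed IB4 density in lamina II
#'
#' After nerve injury, IB4 binding is depleted in a contiguous medio-lateral
#' interval of lamina II within the middle third of the dorsal horn's
#' medio-lateral extent. This locates that interval from segmented IB4 blobs
#' by sliding a window across the middle third, counting blob centroids that
#' fall in lamina II, and taking the contiguous run of windows whose density
#' falls below a contrast criterion relative to the lamina-II-wide median.
#' When no window clears the criterion (sham sections, uniform staining) the
#' default middle-third rectangle is returned, which is where ROIs are placed
#' in sham animals.
#'
#' @param ib4_blobs a [segment_puncta()] result (or data frame with `x_um`,
#'   `y_um` centroids) for the IB4 channel of one side.
#' @param geometry a [generate_geometry()] object.
#' @param side which dorsal horn the blobs come from.
#' @param window_um sliding-window width in microns.
#' @param stride_um window stride in microns.
#' @param contrast detection criterion: a window is "depleted" when its
#'   density is below `contrast` times the median windowed density.
#' @param default_width_um width of the fallback middle-third rectangle.
#' @return named numeric rectangle (x0, x1, y0, y1) in microns spanning
#'   lamina II's depth, with attribute `detected` (logical).
#' @export
detect_lesion_zone <- function(ib4_blobs, geometry,
                               side = c("ipsilateral", "contralateral"),
                               window_um = 30, stride_um = 5,
                               contrast = 0.5, default_width_um = 40) {
  stopifnot(inherits(geometry, "dh_geometry"))
  side <- match.arg(side)
  if (geometry$lii_band_thickness_um <= 0) {
    stop("geometry has no lamina II band", call. = FALSE)
  }
  fallback <- default_middle_third_rect(geometry, side, default_width_um)

  in_lii <- nrow(ib4_blobs) > 0 &
    lamina_at(geometry, ib4_blobs$x_um, ib4_blobs$y_um) == "LII"
  xs <- ib4_blobs$x_um[in_lii]
  if (length(xs) == 0) {
    warning("no IB4 blobs in lamina II; using the default middle-third rectangle",
            call. = FALSE)
    attr(fallback, "detected") <- FALSE
    return(fallback)
  }

  xr <- geometry$side_extent[[side]]
  third_w <- (xr[2] - xr[1]) / 3
  mid <- c(xr[1] + third_w, xr[1] + 2 * third_w)

  # windowed centroid counts across the whole side (median reference), then
  # depletion search restricted to the middle third
  starts <- seq(xr[1], xr[2] - window_um, by = stride_um)
  counts <- vapply(starts, function(s) sum(xs >= s & xs < s + window_um), 0L)
  med <- stats::median(counts)
  in_mid <- starts >= mid[1] - 1e-9 & (starts + window_um) <= mid[2] + 1e-9
  if (!any(in_mid) || med == 0) {
    attr(fallback, "detected") <- FALSE
    return(fallback)
  }
  mid_starts <- starts[in_mid]
  mid_counts <- counts[in_mid]
  depleted <- mid_counts < contrast * med
  if (!any(depleted)) {
    attr(fallback, "detected") <- FALSE
    return(fallback)
  }
  # contiguous run of depleted windows containing the minimum
  i_min <- which.min(mid_counts)
  runs <- rle(depleted)
  ends <- cumsum(runs$lengths)
  begins <- ends - runs$lengths + 1
  run_id <- findInterval(i_min, begins)
  i0 <- begins[run_id]; i1 <- ends[run_id]
  x0 <- mid_starts[i0]
  x1 <- mid_starts[i1] + window_um
  cx <- (x0 + x1) / 2
  y0 <- wm_y_at(geometry, cx) + geometry$li_band_thickness_um
  rect <- c(x0 = x0, x1 = x1, y0 = y0, y1 = y0 + geometry$lii_band_thickness_um)
  attr(rect, "detected") <- TRUE
  rect
}

#' Place the LI and LII quantification rectangles
#'
#' Places the study's two ROIs relative to the white-matter (WM) boundary and
#' the lesion zone: a 15 x 40 um rectangle in lamina I with its longer
#' (40 um) side flush against the WM boundary, and a 30 x 50 um rectangle in
#' lamina II placed horizontally (50 um side medio-lateral) with its near
#' edge 50 um from the WM boundary, both centred on the lesion's
#' medio-lateral centre. On the contralateral side the rectangles mirror
#' their ipsilateral position across the section midline. Because the
#' rectangles must sit *within* the region of decreased staining — which
#' occupies the middle third of the side's medio-lateral extent — each ROI
#' is shifted minimally so it lies inside that middle third; the shift is
#' mirror-symmetric, so contralateral placement remains the exact
#' reflection of the ipsilateral one. Distances from a curved WM boundary
#' are measured at the ROI centre's medio-lateral position; rectangles stay
#' axis-aligned.
#'
#' @param geometry a [generate_geometry()] object.
#' @param lesion lesion rectangle from [detect_lesion_zone()] (or the
#'   geometry's true `lesion_zone`); its medio-lateral centre anchors the
#'   ROIs. Must be expressed in ipsilateral coordinates.
#' @param side placement side; contralateral placement mirrors the lesion
#'   centre across `midline_x_um`.
#' @param placement_mode recorded placement provenance: `"lesion"` (detected
#'   depletion), `"mirrored"`, or `"sham_homotopic"`.
#' @param li_size_um,lii_size_um ROI sizes as (medio-lateral width, depth)
#'   in microns.
#' @param lii_offset_um depth of the LII ROI's near edge below the WM
#'   boundary.
#' @return a tibble of class `dh_rois` with one row per ROI: `lamina`,
#'   `side`, `placement_mode`, `x0`, `x1`, `y0`, `y1`, `area_um2`.
#' @export
place_rois <- function(geometry, lesion,
                       side = c("ipsilateral", "contralateral"),
                       placement_mode = NULL,
                       li_size_um = c(40, 15),
                       lii_size_um = c(50, 30),
                       lii_offset_um = 50) {
  stopifnot(inherits(geometry, "dh_geometry"))
  side <- match.arg(side)
  cx <- (lesion[["x0"]] + lesion[["x1"]]) / 2
  if (side == "contralateral") cx <- mirror_x(geometry, cx)
  if (is.null(placement_mode)) {
    placement_mode <- if (side == "contralateral") "mirrored"
      else if (isTRUE(attr(lesion, "detected"))) "lesion" else "sham_homotopic"
  }
  # keep ROIs inside the side's middle third (the depleted territory);
  # shift minimally when the centred rectangle would protrude
  xr <- geometry$side_extent[[side]]
  third <- c(xr[1] + (xr[2] - xr[1]) / 3, xr[1] + 2 * (xr[2] - xr[1]) / 3)
  centre_in_third <- function(cx, w) {
    if (w <= diff(third)) cx <- min(max(cx, third[1] + w / 2), third[2] - w / 2)
    cx
  }
  cx_li <- centre_in_third(cx, li_size_um[1])
  cx_lii <- centre_in_third(cx, lii_size_um[1])
  y_wm_li <- wm_y_at(geometry, cx_li)
  y_wm_lii <- wm_y_at(geometry, cx_lii)

  li <- c(x0 = cx_li - li_size_um[1] / 2, x1 = cx_li + li_size_um[1] / 2,
          y0 = y_wm_li, y1 = y_wm_li + li_size_um[2])
  lii <- c(x0 = cx_lii - lii_size_um[1] / 2, x1 = cx_lii + lii_size_um[1] / 2,
           y0 = y_wm_lii + lii_offset_um,
           y1 = y_wm_lii + lii_offset_um + lii_size_um[2])
  for (r in list(li, lii)) {
    if (r[["x0"]] < 0 || r[["x1"]] > geometry$width_um ||
        r[["y0"]] < 0 || r[["y1"]] > geometry$height_um) {
      stop(sprintf(
        "ROI exceeds image bounds: [%.1f, %.1f] x [%.1f, %.1f] um in a %.0f x %.0f um image",
        r[["x0"]], r[["x1"]], r[["y0"]], r[["y1"]],
        geometry$width_um, geometry$height_um), call. = FALSE)
    }
  }
  out <- tibble::tibble(
    lamina = c("LI", "LII"),
    side = side,
    placement_mode = placement_mode,
    x0 = c(li[["x0"]], lii[["x0"]]),
    x1 = c(li[["x1"]], lii[["x1"]]),
    y0 = c(li[["y0"]], lii[["y0"]]),
    y1 = c(li[["y1"]], lii[["y1"]])
  )
  out$area_um2 <- (out$x1 - out$x0) * (out$y1 - out$y0)
  class(out) <- c("dh_rois", class(out))
  out
}

#' Default detection parameters for section quantification
#'
#' @param threshold intensity threshold in DN applied to the accentuated
#'   channel, or `NULL` for the robust per-crop default.
#' @param min_area_um2 minimum blob area (size filter).
#' @param mean_area_um2 named per-channel mean single-varicosity areas.
#' @param rule overlap-correction rule.
#' @param structure_scale_um bouton scale for [accentuate()].
#' @param crop_margin_um margin around each ROI crop so morphology has
#'   context at the crop edges.
#' @param lesion_window_um,lesion_stride_um,lesion_contrast lesion-detection
#'   parameters; see [detect_lesion_zone()].
#' @return a named list of parameters.
#' @export
quant_params <- function(threshold = NULL,
                         min_area_um2 = 0.05,
                         mean_area_um2 = c(IB4 = 0.3, GAD65 = 0.2),
                         rule = "total_area",
                         structure_scale_um = 0.55,
                         crop_margin_um = 8,
                         lesion_window_um = 30,
                         lesion_stride_um = 5,
                         lesion_contrast = 0.5) {
  list(threshold = threshold, min_area_um2 = min_area_um2,
       mean_area_um2 = mean_area_um2, rule = rule,
       structure_scale_um = structure_scale_um,
       crop_margin_um = crop_margin_um,
       lesion_window_um = lesion_window_um,
       lesion_stride_um = lesion_stride_um,
       lesion_contrast = lesion_contrast)
}

#' Quantify one two-channel section
#'
#' The full per-section quantification: segment the ipsilateral lamina-II
#' strip of the IB4 channel, detect the lesion zone, place LI/LII ROIs on
#' both sides (contralateral mirrored), count each channel within each ROI
#' (accentuation, segmentation, size filter, overlap correction; a blob
#' belongs to an ROI when its centroid falls inside the rectangle), and
#' convert counts to densities per 100 square microns of nominal ROI area.
#'
#' @param micrograph a [render_micrograph()] or [read_micrograph()] object.
#' @param geometry a [generate_geometry()] object; defaults to the
#'   micrograph's own geometry.
#' @param params a [quant_params()] list.
#' @return a tibble of class `dh_density` with one row per
#'   side x lamina x marker (8 rows): `side`, `lamina`, `marker`,
#'   `raw_blob_count`, `corrected_count`, `roi_area_um2`, `density`
#'   (counts per 100 um^2), `placement_mode`, plus the ROI rectangle
#'   columns. Attribute `lesion` holds the detected lesion rectangle.
#' @export
quantify_section <- function(micrograph, geometry = micrograph$geometry,
                             params = quant_params()) {
  stopifnot(inherits(micrograph, "dh_micrograph"),
            inherits(geometry, "dh_geometry"))
  px <- micrograph$pixel_size_um
  channels <- micrograph$channels

  ib4_name <- if ("IB4" %in% names(channels)) "IB4" else names(channels)[1]

  # lesion detection from the ipsilateral lamina-II strip of the IB4 channel
  strip_blobs <- segment_strip(channels[[ib4_name]], geometry, px,
                               side = "ipsilateral", params = params)
  lesion <- withCallingHandlers(
    detect_lesion_zone(strip_blobs, geometry, side = "ipsilateral",
                       window_um = params$lesion_window_um,
                       stride_um = params$lesion_stride_um,
                       contrast = params$lesion_contrast),
    warning = function(w) invokeRestart("muffleWarning")
  )

  rois <- dplyr::bind_rows(
    place_rois(geometry, lesion, side = "ipsilateral"),
    place_rois(geometry, lesion, side = "contralateral")
  )

  records <- purrr::map_dfr(seq_len(nrow(rois)), function(i) {
    roi <- rois[i, ]
    purrr::map_dfr(names(channels), function(ch) {
      cnt <- count_roi(channels[[ch]], roi, px, params, ch)
      tibble::tibble(
        side = roi$side, lamina = roi$lamina, marker = ch,
        raw_blob_count = cnt$raw_blob_count,
        corrected_count = cnt$corrected_count,
        roi_area_um2 = roi$area_um2,
        density = 100 * cnt$corrected_count / roi$area_um2,
        placement_mode = roi$placement_mode,
        x0 = roi$x0, x1 = roi$x1, y0 = roi$y0, y1 = roi$y1
      )
    })
  })
  attr(records, "lesion") <- lesion
  class(records) <- c("dh_density", class(records))
  records
}

# Segment one side's lamina-II strip of a channel (with margin for the
# morphological context), returning blobs with centroids in image coordinates.
segment_strip <- function(channel, geometry, px, side, params) {
  rect <- lamina_rect(geometry, "LII", side)
  # pad by the crop margin, clamp to the frame
  m <- params$crop_margin_um
  crop <- crop_rect(channel, rect, px, m, geometry)
  acc <- accentuate(crop$img, px, params$structure_scale_um)
  blobs <- segment_puncta(acc, px, threshold = params$threshold,
                          min_area_um2 = params$min_area_um2)
  blobs$x_um <- blobs$x_um + crop$x_off
  blobs$y_um <- blobs$y_um + crop$y_off
  inside <- blobs$x_um >= rect[["x0"]] & blobs$x_um < rect[["x1"]] &
    blobs$y_um >= rect[["y0"]] & blobs$y_um < rect[["y1"]]
  blobs[inside, ]
}

# Count one channel within one ROI row (from place_rois): crop with margin,
# accentuate, segment, keep centroid-inside blobs, overlap-correct.
count_roi <- function(channel, roi, px, params, marker) {
  rect <- c(x0 = roi$x0, x1 = roi$x1, y0 = roi$y0, y1 = roi$y1)
  crop <- crop_rect(channel, rect, px, params$crop_margin_um, NULL)
  acc <- accentuate(crop$img, px, params$structure_scale_um)
  blobs <- segment_puncta(acc, px, threshold = params$threshold,
                          min_area_um2 = params$min_area_um2)
  blobs$x_um <- blobs$x_um + crop$x_off
  blobs$y_um <- blobs$y_um + crop$y_off
  inside <- blobs$x_um >= rect[["x0"]] & blobs$x_um < rect[["x1"]] &
    blobs$y_um >= rect[["y0"]] & blobs$y_um < rect[["y1"]]
  mean_area <- params$mean_area_um2[[marker]] %||% params$mean_area_um2[[1]]
  overlap_correct(blobs[inside, ], mean_area, params$rule)
}

# Crop a channel matrix to a micron rectangle plus margin; returns the crop
# and the micron offset of its top-left corner.
crop_rect <- function(channel, rect, px, margin_um, geometry) {
  j0 <- max(1L, floor((rect[["x0"]] - margin_um) / px) + 1L)
  j1 <- min(ncol(channel), ceiling((rect[["x1"]] + margin_um) / px))
  i0 <- max(1L, floor((rect[["y0"]] - margin_um) / px) + 1L)
  i1 <- min(nrow(channel), ceiling((rect[["y1"]] + margin_um) / px))
  list(img = channel[i0:i1, j0:j1, drop = FALSE],
       x_off = (j0 - 1L) * px, y_off = (i0 - 1L) * px)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
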
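#' Parametric model of one transverse dorsal-horn section
#'
#' Builds the geometric scaffold on which synthetic micrographs are rendered
#' and quantification ROIs are placed: the white-matter (WM) boundary, the
#' lamina I and lamina II bands beneath it, the medio-lateral thirds of each
#' side, and the "lesion zone" — the medio-lateral interval of lamina II in
#' which IB4 binding is depleted after nerve injury.
#'
#' The coordinate convention is fixed: origin at the top-left corner of the
#' image, x running medio-laterally (left edge = lateral edge of the
#' ipsilateral side), y running dorso-ventrally (downwards), both in microns.
#' The section contains both dorsal horns; `midline_x_um` is the mirror axis
#' used for contralateral ROI placement. Pixels are half-open bins:
#' pixel (i, j) covers `[(j-1), j) x [(i-1), i)` in pixel units.
#'
#' The WM boundary is a polyline `y = wm_y_um + wm_curve_amp_um * sin(pi * x / width)`
#' sampled every pixel column; with the default amplitude 0 it is flat.
#' Lamina I occupies the band within `li_band_thickness_um` of the boundary
#' (measured along the local boundary normal), lamina II the next
#' `lii_band_thickness_um`.
#'
#' @param width_um,height_um physical extent of the section image (microns).
#'   The width spans both dorsal horns; the midline sits at `width_um / 2`.
#' @param pixel_size_um isotropic pixel size in microns per pixel.
#' @param wm_y_um depth of the WM boundary at the lateral edges (microns).
#' @param wm_curve_amp_um amplitude of the sinusoidal bowing of the WM
#'   boundary (microns); 0 gives a flat boundary.
#' @param li_band_thickness_um,lii_band_thickness_um laminar band depths
#'   (microns), measured from the WM boundary.
#' @param lesion_width_um medio-lateral width of the lesion zone (microns),
#'   or `NULL` (default) to fill the middle third of the side. The zone is
#'   centred on the middle third of the ipsilateral side and spans the full
#'   depth of lamina II. The default matches the anatomy: the IB4 depletion
#'   occupies the intermediate third of the medio-lateral extent (the
#'   sciatic projection territory), and the 50 um quantification rectangle
#'   is placed *within* that region.
#' @param lesion_offset_um signed medio-lateral offset of the lesion centre
#'   from the middle-third centre (microns). Must keep the zone inside the
#'   middle third.
#' @param seed integer seed; geometry construction is deterministic given
#'   `seed` and the parameters (the seed is reserved for future stochastic
#'   geometry components and recorded in the object).
#'
#' @return An object of class `dh_geometry`: a list with fields
#'   `pixel_size_um`, `image_shape` (rows, cols), `width_um`, `height_um`,
#'   `wm_boundary` (two-column matrix of (x, y) in microns, one vertex per
#'   pixel column), `wm_y_um`, `wm_curve_amp_um`, `li_band_thickness_um`,
#'   `lii_band_thickness_um`, `midline_x_um`, `lesion_zone` (named numeric
#'   rectangle: x0, x1, y0, y1 in microns) and `side_extent` (per-side x
#'   ranges).
#'
#' @examples
#' geom <- generate_geometry(seed = 1)
#' geom$lesion_zone
#' @export
generate_geometry <- function(width_um = 600,
                              height_um = 200,
                              pixel_size_um = 0.1,
                              wm_y_um = 20,
                              wm_curve_amp_um = 0,
                              li_band_thickness_um = 20,
                              lii_band_thickness_um = 80,
                              lesion_width_um = NULL,
                              lesion_offset_um = 0,
                              seed = 1L) {
  stopifnot(pixel_size_um > 0, width_um > 0, height_um > 0)
  if (li_band_thickness_um <= 0 || lii_band_thickness_um <= 0) {
    stop("laminar band thicknesses must be strictly positive", call. = FALSE)
  }
  ncol_px <- round(width_um / pixel_size_um)
  nrow_px <- round(height_um / pixel_size_um)

  midline_x <- width_um / 2
  if (midline_x < 3 * max(lesion_width_um %||% 0, 50)) {
    stop("image width too small for the middle-third lesion zone and ROIs",
         call. = FALSE)
  }

  # WM boundary polyline, one vertex per pixel column centre
  xs <- (seq_len(ncol_px) - 0.5) * pixel_size_um
  ys <- wm_y_um + wm_curve_amp_um * sin(pi * xs / width_um)
  wm_boundary <- cbind(x = xs, y = ys)

  # ipsilateral side is x in [0, midline); medio-lateral thirds of that side
  side_w <- midline_x
  third_w <- side_w / 3
  mid_third <- c(third_w, 2 * third_w)
  if (is.null(lesion_width_um)) lesion_width_um <- third_w
  lesion_cx <- mean(mid_third) + lesion_offset_um
  lesion_x0 <- lesion_cx - lesion_width_um / 2
  lesion_x1 <- lesion_cx + lesion_width_um / 2
  if (lesion_x0 < mid_third[1] - 1e-9 || lesion_x1 > mid_third[2] + 1e-9) {
    stop("lesion zone must lie within the middle third of the medio-lateral extent",
         call. = FALSE)
  }

  # lesion zone spans the depth of the LII band at its medio-lateral centre
  wm_at_cx <- wm_y_um + wm_curve_amp_um * sin(pi * lesion_cx / width_um)
  lesion_y0 <- wm_at_cx + li_band_thickness_um
  lesion_y1 <- wm_at_cx + li_band_thickness_um + lii_band_thickness_um

  max_wm_y <- max(ys)
  if (max_wm_y + li_band_thickness_um + lii_band_thickness_um > height_um) {
    stop("image height too small: laminar bands extend below the image", call. = FALSE)
  }
  # both quantification ROIs must fit: LII ROI reaches 50 + 30 um below the WM
  if (max_wm_y + 80 > height_um) {
    stop("image extent too small to contain the LII ROI at 50 um from the white matter",
         call. = FALSE)
  }

  structure(
    list(
      pixel_size_um = pixel_size_um,
      image_shape = c(rows = nrow_px, cols = ncol_px),
      width_um = ncol_px * pixel_size_um,
      height_um = nrow_px * pixel_size_um,
      wm_boundary = wm_boundary,
      wm_y_um = wm_y_um,
      wm_curve_amp_um = wm_curve_amp_um,
      li_band_thickness_um = li_band_thickness_um,
      lii_band_thickness_um = lii_band_thickness_um,
      midline_x_um = midline_x,
      lesion_zone = c(x0 = lesion_x0, x1 = lesion_x1, y0 = lesion_y0, y1 = lesion_y1),
      side_extent = list(ipsilateral = c(0, midline_x),
                         contralateral = c(midline_x, ncol_px * pixel_size_um)),
      seed = as.integer(seed)
    ),
    class = "dh_geometry"
  )
}

#' @export
print.dh_geometry <- function(x, ...) {
  cat("<dh_geometry> ", x$width_um, " x ", x$height_um, " um @ ",
      x$pixel_size_um, " um/px (", x$image_shape[["rows"]], " x ",
      x$image_shape[["cols"]], " px)\n", sep = "")
  cat("  WM boundary at y = ", x$wm_y_um, " um (curve amp ", x$wm_curve_amp_um,
      "), LI ", x$li_band_thickness_um, " um, LII ", x$lii_band_thickness_um,
      " um\n", sep = "")
  cat("  lesion zone x [", round(x$lesion_zone[["x0"]], 1), ", ",
      round(x$lesion_zone[["x1"]], 1), "] um, midline at ",
      x$midline_x_um, " um\n", sep = "")
  invisible(x)
}

#' Depth of the white-matter boundary at a medio-lateral position
#'
#' @param geometry a [generate_geometry()] object.
#' @param x_um medio-lateral positions (microns).
#' @return boundary depth(s) in microns.
#' @keywords internal
wm_y_at <- function(geometry, x_um) {
  geometry$wm_y_um + geometry$wm_curve_amp_um * sin(pi * x_um / geometry$width_um)
}

#' Mirror a medio-lateral coordinate across the section midline
#'
#' @param geometry a [generate_geometry()] object.
#' @param x_um medio-lateral positions (microns).
#' @return mirrored positions: `2 * midline - x`.
#' @export
mirror_x <- function(geometry, x_um) {
  2 * geometry$midline_x_um - x_um
}

#' Laminar band of each point, given the section geometry
#'
#' Classifies (x, y) positions into white matter, lamina I, lamina II or
#' deeper tissue by their depth below the local WM boundary.
#'
#' @param geometry a [generate_geometry()] object.
#' @param x_um,y_um point coordinates in microns.
#' @return character vector: `"WM"`, `"LI"`, `"LII"` or `"deep"`.
#' @export
lamina_at <- function(geometry, x_um, y_um) {
  depth <- y_um - wm_y_at(geometry, x_um)
  out <- rep("deep", length(depth))
  out[depth < 0] <- "WM"
  out[depth >= 0 & depth < geometry$li_band_thickness_um] <- "LI"
  out[depth >= geometry$li_band_thickness_um &
        depth < geometry$li_band_thickness_um + geometry$lii_band_thickness_um] <- "LII"
  out
}

#' Rectangle (in microns) of a laminar band on one side
#'
#' Axis-aligned bounding region of a lamina restricted to one side of the
#' section. For curved boundaries the returned rectangle uses the boundary
#' depth at the side's centre; punctum membership should be decided with
#' [lamina_at()].
#'
#' @param geometry a [generate_geometry()] object.
#' @param lamina `"LI"` or `"LII"`.
#' @param side `"ipsilateral"` or `"contralateral"`.
#' @return named numeric rectangle (x0, x1, y0, y1) in microns.
#' @export
lamina_rect <- function(geometry, lamina = c("LI", "LII"),
                        side = c("ipsilateral", "contralateral")) {
  lamina <- match.arg(lamina)
  side <- match.arg(side)
  xr <- geometry$side_extent[[side]]
  cx <- mean(xr)
  y_wm <- wm_y_at(geometry, cx)
  if (lamina == "LI") {
    y0 <- y_wm
    y1 <- y_wm + geometry$li_band_thickness_um
  } else {
    y0 <- y_wm + geometry$li_band_thickness_um
    y1 <- y0 + geometry$lii_band_thickness_um
  }
  c(x0 = xr[1], x1 = xr[2], y0 = y0, y1 = y1)
}

#' Default middle-third rectangle used when no IB4 depletion is detectable
#'
#' In sham sections there is no lesion; ROIs are placed where the lesion
#' normally occurs, i.e. at the centre of the middle third of the
#' medio-lateral extent.
#'
#' @param geometry a [generate_geometry()] object.
#' @param side which dorsal horn.
#' @param width_um medio-lateral width of the returned rectangle.
#' @return named numeric rectangle (x0, x1, y0, y1) spanning LII's depth.
#' @export
default_middle_third_rect <- function(geometry,
                                      side = c("ipsilateral", "contralateral"),
                                      width_um = 40) {
  side <- match.arg(side)
  xr <- geometry$side_extent[[side]]
  third_w <- (xr[2] - xr[1]) / 3
  cx <- xr[1] + 1.5 * third_w
  y_wm <- wm_y_at(geometry, cx)
  y0 <- y_wm + geometry$li_band_thickness_um
  c(x0 = cx - width_um / 2, x1 = cx + width_um / 2,
    y0 = y0, y1 = y0 + geometry$lii_band_thickness_um)
}

rect_area <- function(rect) {
  (rect[["x1"]] - rect[["x0"]]) * (rect[["y1"]] - rect[["y0"]])
}

rect_intersect_area <- function(a, b) {
  w <- max(0, min(a[["x1"]], b[["x1"]]) - max(a[["x0"]], b[["x0"]]))
  h <- max(0, min(a[["y1"]], b[["y1"]]) - max(a[["y0"]], b[["y0"]]))
  w * h
}
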
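test_that("ROIs have the study's exact sizes and placement", {
  geom <- generate_geometry(seed = 1)  # flat WM boundary at y = 20
  lesion <- geom$lesion_zone
  rois <- place_rois(geom, lesion, side = "ipsilateral")
  li <- rois[rois$lamina == "LI", ]
  lii <- rois[rois$lamina == "LII", ]
  expect_equal(li$area_um2, 600)    # 15 x 40 um
  expect_equal(lii$area_um2, 1500)  # 30 x 50 um
  # LI flush with the WM boundary, 40 um side along it
  expect_equal(li$y0, 20)
  expect_equal(li$x1 - li$x0, 40)
  expect_equal(li$y1 - li$y0, 15)
  # LII near edge 50 um below the WM boundary, long side horizontal
  expect_equal(lii$y0, 70)
  expect_equal(lii$x1 - lii$x0, 50)
  expect_equal(lii$y1 - lii$y0, 30)
})

test_that("contralateral ROIs mirror the ipsilateral position", {
  geom <- generate_geometry(seed = 1)
  ipsi <- place_rois(geom, geom$lesion_zone, side = "ipsilateral")
  contra <- place_rois(geom, geom$lesion_zone, side = "contralateral")
  cx_i <- (ipsi$x0 + ipsi$x1) / 2
  cx_c <- (contra$x0 + contra$x1) / 2
  expect_equal(cx_c, 2 * geom$midline_x_um - cx_i)
  expect_equal(contra$placement_mode, rep("mirrored", 2))
  # mirroring the mirrored centre returns the original
  expect_equal(mirror_x(geom, cx_c), cx_i)
})

test_that("out-of-bounds placement fails with a placement report", {
  geom <- generate_geometry(seed = 1)
  # an LII offset beyond the frame depth cannot be placed
  expect_error(place_rois(geom, geom$lesion_zone, lii_offset_um = 250),
               "exceeds image bounds")
  # laterally displaced anchors are pulled back inside the middle third
  shifted <- place_rois(geom, c(x0 = -40, x1 = 10, y0 = 40, y1 = 120))
  third <- c(100, 200)
  expect_true(all(shifted$x0 >= third[1] & shifted$x1 <= third[2]))
})

test_that("lesion detection recovers a synthetic depletion interval", {
  geom <- test_geometry(seed = 1)
  cfg <- default_timecourse()
  sim <- simulate_section_fields(geom, cfg, day = 21, group = "cuff",
                                 seed = 3)
  mg <- render_micrograph(geom, sim$fields, noise_model(), seed = 4)
  blobs <- dorsalhorn:::segment_strip(mg$channels$IB4, geom, 0.1,
                                      "ipsilateral", quant_params())
  lesion <- detect_lesion_zone(blobs, geom)
  expect_true(attr(lesion, "detected"))
  truth <- geom$lesion_zone
  overlap <- min(lesion[["x1"]], truth[["x1"]]) - max(lesion[["x0"]], truth[["x0"]])
  expect_gte(overlap / (lesion[["x1"]] - lesion[["x0"]]), 0.8)
})

test_that("uniform or empty IB4 staining falls back to the middle third", {
  geom <- test_geometry(seed = 1)
  # uniform staining: no window clears the contrast criterion
  f <- sample_puncta(lamina_rect(geom, "LII", "ipsilateral"), 20, 0.3,
                     seed = 5)
  blobs <- tibble::tibble(x_um = f$x_um, y_um = f$y_um)
  lesion <- detect_lesion_zone(blobs, geom)
  expect_false(attr(lesion, "detected"))
  expect_equal((lesion[["x0"]] + lesion[["x1"]]) / 2, geom$midline_x_um / 2)

  empty <- tibble::tibble(x_um = numeric(), y_um = numeric())
  expect_warning(lesion2 <- detect_lesion_zone(empty, geom), "no IB4 blobs")
  expect_false(attr(lesion2, "detected"))
})

test_that("a blank section quantifies to eight zero-density records", {
  geom <- test_geometry(seed = 1)
  empty <- tibble::tibble(x_um = numeric(), y_um = numeric(),
                          area_um2 = numeric(), amplitude = numeric(),
                          channel = character())
  mg <- render_micrograph(geom, list(IB4 = empty, GAD65 = empty),
                          noise_model(), seed = 1)
  rec <- quantify_section(mg)
  expect_equal(nrow(rec), 8)
  expect_true(all(rec$density == 0))
  expect_setequal(unique(rec$side), c("ipsilateral", "contralateral"))
  expect_setequal(unique(rec$lamina), c("LI", "LII"))
})

test_that("a mirror-symmetric section gives identical counts on both sides", {
  geom <- test_geometry(seed = 1)
  cfg <- default_timecourse(animal_cv = 0, section_cv = 0)
  sim <- simulate_section_fields(geom, cfg, day = 21, group = "sham",
                                 seed = 6)
  mg <- render_micrograph(geom, sim$fields, noise_model(background_sd = 0),
                          seed = 7)
  # overwrite the contralateral half with the mirrored ipsilateral half
  for (ch in names(mg$channels)) {
    m <- mg$channels[[ch]]
    half <- ncol(m) / 2
    m[, (half + 1):ncol(m)] <- m[, half:1]
    mg$channels[[ch]] <- m
  }
  rec <- quantify_section(mg)
  wide <- tidyr::pivot_wider(rec[, c("side", "lamina", "marker",
                                     "corrected_count")],
                             names_from = side,
                             values_from = corrected_count)
  expect_equal(wide$ipsilateral, wide$contralateral)
})

test_that("density is invariant to translating section and geometry together", {
  base <- test_geometry(seed = 1)
  shifted <- test_geometry(wm_y_um = 30, seed = 1)
  f <- sample_puncta(lamina_rect(base, "LII", "ipsilateral"), 15, 0.3,
                     seed = 8)
  f2 <- dplyr::mutate(f, y_um = y_um + 10)
  mg1 <- render_micrograph(base, list(IB4 = f),
                           noise_model(background_sd = 0), seed = 1)
  mg2 <- render_micrograph(shifted, list(IB4 = f2),
                           noise_model(background_sd = 0), seed = 1)
  r1 <- quantify_section(mg1)
  r2 <- quantify_section(mg2)
  expect_equal(r1$density, r2$density)
})

test_that("section quantification recovers a known lamina II density", {
  geom <- test_geometry(seed = 1)
  cfg <- default_timecourse(animal_cv = 0, section_cv = 0,
                            baseline_density = list(IB4 = c(LI = 4, LII = 20),
                                                    GAD65 = c(LI = 12, LII = 12)))
  dens <- vapply(1:20, function(s) {
    sim <- simulate_section_fields(geom, cfg, day = 21, group = "sham",
                                   seed = 40 + s)
    mg <- render_micrograph(geom, sim$fields, noise_model(), seed = 90 + s)
    rec <- quantify_section(mg)
    rec$density[rec$side == "ipsilateral" & rec$lamina == "LII" &
                  rec$marker == "GAD65"]
  }, 0)
  expect_lt(abs(mean(dens) - 12) / 12, 0.15)
})
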
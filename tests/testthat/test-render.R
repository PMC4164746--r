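test_that("empty fields with zero read noise give a constant background", {
  geom <- test_geometry()
  empty <- tibble::tibble(x_um = numeric(), y_um = numeric(),
                          area_um2 = numeric(), amplitude = numeric(),
                          channel = character())
  mg <- render_micrograph(geom, list(IB4 = empty),
                          noise_model(background_sd = 0), seed = 1)
  expect_true(all(mg$channels$IB4 == 100L))
})

test_that("a punctum's rendered area matches its configured area", {
  geom <- test_geometry()
  # centre on a pixel centre so disc quantisation is deterministic
  f <- tibble::tibble(x_um = 100.05, y_um = 70.05, area_um2 = 0.2,
                      amplitude = 800, channel = "GAD65")
  mg <- render_micrograph(geom, list(GAD65 = f),
                          noise_model(background_sd = 0), seed = 1)
  above <- sum(mg$channels$GAD65 > 100L)
  px_area <- geom$pixel_size_um^2
  expect_lt(abs(above * px_area - 0.2), 0.02)  # within ~2 px of 0.2 um^2
})

test_that("default rendering never saturates the 12-bit range", {
  geom <- test_geometry()
  f <- sample_puncta(c(x0 = 50, x1 = 150, y0 = 45, y1 = 110), 20, 0.3,
                     seed = 3)
  mg <- render_micrograph(geom, list(IB4 = f), noise_model(), seed = 4)
  expect_lt(max(mg$channels$IB4), 4095)
  expect_error(noise_model(background_level = 3000, amp_range = c(500, 1500)),
               "saturate")
})

test_that("rendering conserves well-separated puncta", {
  geom <- test_geometry()
  f <- grid_puncta(40, 0.25, c(x0 = 60, x1 = 160, y0 = 50, y1 = 110))
  mg <- render_micrograph(geom, list(IB4 = f),
                          noise_model(background_sd = 0), seed = 1)
  mask <- mg$channels$IB4 > 100L
  expect_equal(length(flood_sizes(mask)), 40)
})

test_that("rendering is deterministic and clips out-of-frame centres with a warning", {
  geom <- test_geometry()
  f <- sample_puncta(c(x0 = 50, x1 = 90, y0 = 50, y1 = 90), 10, 0.3, seed = 5)
  m1 <- render_micrograph(geom, list(IB4 = f), noise_model(), seed = 9)
  m2 <- render_micrograph(geom, list(IB4 = f), noise_model(), seed = 9)
  expect_identical(m1$channels, m2$channels)

  f_out <- tibble::tibble(x_um = -3, y_um = 50, area_um2 = 0.3,
                          amplitude = 700, channel = "IB4")
  expect_warning(render_micrograph(geom, list(IB4 = f_out), noise_model(),
                                   seed = 1),
                 "outside the image")
})
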
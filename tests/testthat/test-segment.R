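test_that("blank and over-thresholded images yield no blobs", {
  img <- matrix(0, 50, 50)
  expect_equal(nrow(segment_puncta(img, 0.1, threshold = 10)), 0)
  img[10:12, 10:12] <- 50
  expect_equal(nrow(segment_puncta(img, 0.1, threshold = 100)), 0)
})

test_that("the minimum-size filter removes sub-0.05 um^2 objects", {
  img <- matrix(0, 60, 60)
  img[10:12, 10] <- 50           # 3 px = 0.03 um^2 at 0.1 um/px -> filtered
  expect_equal(nrow(segment_puncta(img, 0.1, threshold = 10)), 0)
  img[30:34, 30] <- 50           # 5 px = 0.05 um^2 -> kept
  b <- segment_puncta(img, 0.1, threshold = 10)
  expect_equal(nrow(b), 1)
  expect_equal(b$area_um2, 0.05)
})

test_that("disjoint discs are counted and measured individually", {
  geom <- test_geometry()
  f <- grid_puncta(10, 0.2, c(x0 = 60, x1 = 120, y0 = 50, y1 = 80))
  mg <- render_micrograph(geom, list(IB4 = f),
                          noise_model(background_sd = 0), seed = 1)
  b <- segment_puncta(mg$channels$IB4, 0.1, threshold = 100)
  expect_equal(nrow(b), 10)
  expect_true(all(abs(b$area_um2 - 0.2) <= 0.02))
})

test_that("segmentation agrees with an independent flood-fill oracle", {
  set.seed(31)
  for (rep in 1:5) {
    img <- matrix(0, 120, 120)
    n <- sample(5:15, 1)
    for (k in seq_len(n)) {
      i <- sample(10:110, 1); j <- sample(10:110, 1)
      r <- sample(2:4, 1)
      ii <- pmax(1, i - r):pmin(120, i + r)
      jj <- pmax(1, j - r):pmin(120, j + r)
      img[ii, jj] <- 60
    }
    sizes <- flood_sizes(img > 30)
    b <- segment_puncta(img, 0.1, threshold = 30, min_area_um2 = 0)
    expect_equal(nrow(b), length(sizes))
    expect_equal(sort(b$n_px), sort(sizes))
  }
})

test_that("overlap correction follows the mean-area rule", {
  one <- tibble::tibble(area_um2 = 0.2)
  expect_equal(overlap_correct(one, 0.2)$corrected_count, 1)
  expect_equal(overlap_correct(one, 0.2, "per_blob")$corrected_count, 1)

  big <- tibble::tibble(area_um2 = 0.6)
  expect_equal(overlap_correct(big, 0.3)$corrected_count, 2)
  expect_equal(overlap_correct(big, 0.3, "per_blob")$corrected_count, 2)

  # max(1, round(1.25)) + max(1, round(0.5)) with round-half-to-even
  two <- tibble::tibble(area_um2 = c(0.25, 0.1))
  expect_equal(overlap_correct(two, 0.2, "per_blob")$corrected_count, 2)
  expect_equal(overlap_correct(two, 0.2)$corrected_count, 2)

  expect_error(overlap_correct(one, 0), "positive")
  expect_error(overlap_correct(one, -0.2), "positive")
})

test_that("corrected counts never fall below raw counts", {
  set.seed(11)
  for (rep in 1:20) {
    blobs <- tibble::tibble(area_um2 = rlnorm(sample(1:40, 1), log(0.25), 0.5))
    for (rule in c("total_area", "per_blob")) {
      cc <- overlap_correct(blobs, 0.3, rule)
      expect_gte(cc$corrected_count, cc$raw_blob_count)
    }
  }
})

test_that("per-blob correction is the identity when no blob exceeds 1.5x the mean", {
  set.seed(12)
  for (rep in 1:10) {
    blobs <- tibble::tibble(area_um2 = runif(sample(1:30, 1), 0.05, 0.449))
    cc <- overlap_correct(blobs, 0.3, "per_blob")
    expect_equal(cc$corrected_count, cc$raw_blob_count)
  }
})

test_that("count_channel composes the stages and respects monotonicity", {
  geom <- test_geometry()
  f <- grid_puncta(50, 0.25, c(x0 = 60, x1 = 200, y0 = 50, y1 = 110))
  mg <- render_micrograph(geom, list(IB4 = f), noise_model(), seed = 2)
  crop <- mg$channels$IB4[401:1200, 501:2100]
  cnt <- count_channel(crop, 0.1, 0.3)
  expect_equal(cnt$corrected_count, 50)

  blank <- matrix(100L, 200, 200)
  expect_equal(count_channel(blank, 0.1, 0.3)$corrected_count, 0)

  # adding a disjoint punctum never decreases the corrected count
  f2 <- dplyr::bind_rows(f, tibble::tibble(x_um = 300, y_um = 70,
                                           area_um2 = 0.3, amplitude = 900,
                                           channel = "IB4"))
  mg2 <- render_micrograph(geom, list(IB4 = f2), noise_model(), seed = 2)
  cnt2 <- count_channel(mg2$channels$IB4[401:1200, 501:3200], 0.1, 0.3)
  expect_gte(cnt2$corrected_count, cnt$corrected_count)
})

test_that("a saturated channel warns and returns an empty count", {
  img <- matrix(4095L, 100, 100)
  expect_warning(res <- count_channel(img, 0.1, 0.3), "saturated")
  expect_equal(res$corrected_count, 0)
})
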
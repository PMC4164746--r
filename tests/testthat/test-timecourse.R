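test_that("the packaged time-course encodes the reported minima and recovery", {
  cfg <- default_timecourse()
  look <- function(day, lamina, marker)
    dorsalhorn:::lookup_pct(cfg, day, "cuff", "ipsilateral", lamina, marker)
  expect_equal(look(21, "LII", "IB4"), 1.5)
  expect_equal(look(56, "LII", "IB4"), 52.1)
  expect_equal(look(21, "LII", "GAD65"), 34.1)
  expect_equal(look(56, "LII", "GAD65"), 72)
  expect_equal(look(21, "LI", "GAD65"), 63.1)
  bl <- function(day, endpoint)
    dorsalhorn:::lookup_behavior_pct(cfg, day, "cuff", "ipsilateral", endpoint)
  expect_equal(bl(21, "von_frey"), 16.3)
  expect_equal(bl(28, "hargreaves"), 70.1)
  # sham is 100 everywhere by construction
  sham <- cfg$histology_pct[cfg$histology_pct$group == "sham", ]
  expect_true(all(sham$pct == 100))
  expect_equal(cfg$sections_per_animal, 6)
})

test_that("non-100 sham percentages are rejected", {
  cfg <- default_timecourse()
  h <- cfg$histology_pct
  h$pct[h$group == "sham"][1] <- 90
  expect_error(timecourse_config(histology_pct = h,
                                 behavior_pct = cfg$behavior_pct),
               "sham")
})

test_that("sham sections realise the baseline densities exactly (no variance components)", {
  geom <- test_geometry(seed = 1)
  cfg <- default_timecourse(animal_cv = 0, section_cv = 0)
  sim <- simulate_section_fields(geom, cfg, day = 21, group = "sham",
                                 seed = 2)
  lii_ib4 <- sim$truth[sim$truth$lamina == "LII" & sim$truth$marker == "IB4", ]
  expect_equal(lii_ib4$true_density, rep(20, 2))  # both sides at baseline
  li_gad <- sim$truth[sim$truth$lamina == "LI" & sim$truth$marker == "GAD65", ]
  expect_equal(li_gad$true_density, rep(12, 2))
})

test_that("cuff sections scale the lesion interval only, in lamina II", {
  geom <- test_geometry(seed = 1)
  cfg <- default_timecourse(animal_cv = 0, section_cv = 0)
  sim <- simulate_section_fields(geom, cfg, day = 21, group = "cuff",
                                 seed = 3)
  lii <- sim$truth[sim$truth$lamina == "LII" & sim$truth$marker == "IB4", ]
  expect_equal(lii$true_density[lii$side == "ipsilateral"], 20 * 0.015)
  expect_equal(lii$true_density[lii$side == "contralateral"], 20)
  # flanking lamina II outside the lesion stays at baseline: puncta exist
  # medial and lateral of the lesion interval on the ipsilateral side
  f <- sim$fields$IB4
  lz <- geom$lesion_zone
  in_lii <- lamina_at(geom, f$x_um, f$y_um) == "LII" &
    f$x_um < geom$midline_x_um
  expect_gt(sum(in_lii & f$x_um < lz[["x0"]]), 0)
  expect_gt(sum(in_lii & f$x_um > lz[["x1"]]), 0)
  inside <- sum(in_lii & f$x_um >= lz[["x0"]] & f$x_um <= lz[["x1"]])
  area_lesion <- (lz[["x1"]] - lz[["x0"]]) * geom$lii_band_thickness_um
  expect_lt(inside / (area_lesion / 100), 2)  # ~0.3 per 100 um^2 expected
})

test_that("cohort simulation is deterministic and animal effects couple markers", {
  cfg <- default_timecourse(coupling = 1, animal_cv = 0.5)
  af <- replicate(200, dorsalhorn:::animal_effects(cfg, c("IB4", "GAD65"),
                                                   sample.int(1e6, 1)))
  # full coupling: identical effects for the two markers
  expect_equal(af[1, ], af[2, ])
  cfg0 <- default_timecourse(coupling = 0, animal_cv = 0.5)
  af0 <- vapply(1:300, function(s)
    dorsalhorn:::animal_effects(cfg0, c("IB4", "GAD65"), s), c(a = 0, b = 0))
  expect_lt(abs(cor(log(af0[1, ]), log(af0[2, ]))), 0.2)
  # mean-one on the natural scale
  expect_lt(abs(mean(af0[1, ]) - 1), 0.1)
})
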
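test_that("stage presets carry the stage ground truths", {
  green <- leaf_preset("green")
  yellow <- leaf_preset("yellow")
  red <- leaf_preset("red")
  expect_equal(green$attenuation_db_per_um, -0.78)
  expect_equal(yellow$attenuation_db_per_um, -1.10)
  expect_equal(red$attenuation_db_per_um, -1.20)
  expect_gte(length(green$layers), 3)   # cuticle, upper epidermis, palisade
  expect_length(yellow$layers, 2)       # merged second interface
  # default geometry: 813 A-scans, 750 depth px, 200 px = 492 x 533 um
  expect_equal(green$n_alines, 813L)
  expect_equal(green$n_depth_px, 750L)
  expect_equal(200 * green$lateral_pitch_um, 492)
  expect_equal(200 * green$axial_pitch_um, 533)
  # heterogeneity contrast increases monotonically with senescence
  expect_lt(green$texture_contrast, yellow$texture_contrast)
  expect_lt(yellow$texture_contrast, red$texture_contrast)
  for (cfg in list(green, yellow, red))
    expect_lte(cfg$attenuation_db_per_um, 0)
  expect_error(leaf_preset("brown"), "unknown stage")
})

test_that("config invariants are enforced", {
  expect_error(layer_spec("x", 0, -5), "thickness")
  expect_error(layer_spec("x", -1, 5), "top_depth")
  expect_error(phantom_config("s", list(layer_spec("a", 0, 10)), 0.5),
               "attenuation")
  expect_error(phantom_config("s", list(layer_spec("a", 50, 10),
                                        layer_spec("b", 0, 10)), -1),
               "ordered")
  expect_error(phantom_config("s", list(layer_spec("a", 0, 100),
                                        layer_spec("b", 50, 10)), -1),
               "overlap")
})

test_that("expected_profile places interface peaks and obeys the decay law", {
  # single interface at 100 um, zero attenuation: maximum at that depth
  cfg <- phantom_config("toy",
                        list(layer_spec("deep", 100, 50,
                                        interface_reflectivity = 50,
                                        bulk_reflectivity = 0.01)),
                        attenuation_db_per_um = 0, surface_depth_px = 5L,
                        n_alines = 16L, n_depth_px = 120L)
  prof <- expected_profile(cfg)
  peak_row <- which.max(prof$values)
  expect_equal((peak_row - cfg$surface_depth_px) * cfg$axial_pitch_um, 100,
               tolerance = cfg$axial_pitch_um)
  # no interfaces, attenuation -1: 10*log10 is linear with slope -1 dB/um
  cfg2 <- phantom_config("toy2", list(layer_spec("bulk", 0, 1000)),
                         attenuation_db_per_um = -1, surface_depth_px = 5L,
                         n_alines = 8L, n_depth_px = 200L)
  prof2 <- expected_profile(cfg2)
  tissue <- seq(cfg2$surface_depth_px, cfg2$n_depth_px)
  db <- 10 * log10(prof2$values[tissue])
  slopes <- diff(db) / cfg2$axial_pitch_um
  expect_equal(slopes, rep(-1, length(slopes)), tolerance = 1e-9)
})

test_that("green preset has exactly two sub-surface maxima in the first 350 um", {
  cfg <- leaf_preset("green")
  v <- expected_profile(cfg)$values
  lmax <- which(diff(sign(diff(v))) == -2) + 1
  z <- (lmax - cfg$surface_depth_px) * cfg$axial_pitch_um
  expect_equal(sum(z > 0 & z <= 350), 2)
})

test_that("generate_bscan honours the speckle model and is deterministic", {
  cfg <- flat_config(contrast = 0.4, n_alines = 48L, n_depth_px = 96L,
                     surface_depth_px = 10L)
  # speckle = none, no heterogeneity: every A-line is the expected profile
  cfg0 <- flat_config(contrast = 0, n_alines = 48L, n_depth_px = 96L,
                      surface_depth_px = 10L)
  m0 <- generate_bscan(within_none(cfg0), seed = 1)
  prof0 <- expected_profile(cfg0)$values
  expect_equal(m0, matrix(prof0, 96, 48), ignore_attr = TRUE)
  # with heterogeneity: the multiplicative field has unit lateral mean over
  # the central analysis window at every tissue depth
  m <- generate_bscan(within_none(cfg), seed = 1)
  prof <- expected_profile(cfg)$values
  tissue <- cfg$surface_depth_px:cfg$n_depth_px
  field <- m[tissue, ] / prof[tissue]
  expect_equal(rowMeans(field), rep(1, length(tissue)), tolerance = 1e-12)
  expect_equal(dim(m), c(96L, 48L))
  b1 <- generate_bscan(cfg, seed = 99)
  b2 <- generate_bscan(cfg, seed = 99)
  expect_identical(b1, b2)
  expect_false(identical(b1, generate_bscan(cfg, seed = 100)))
  expect_true(all(b1 >= 0))
})

test_that("speckle means converge to the configured mean field", {
  cfg <- flat_config(attenuation = -0.5, contrast = 0.3, n_alines = 24L,
                     n_depth_px = 64L, surface_depth_px = 8L, seed = 5L)
  m <- generate_bscan(within_none(cfg), seed = 1)
  stack <- generate_stack(cfg, n_frames = 500, seed = 42)
  avg <- average_frames(stack)
  tissue <- cfg$surface_depth_px:cfg$n_depth_px
  rel <- abs(avg[tissue, ] / m[tissue, ] - 1)
  expect_lt(mean(rel), 0.05)        # mean absolute relative error over pixels
  expect_lt(rel[30, 12], 0.05)      # and at a fixed pixel
})

test_that("stacks are reproducible and consistent with single B-scans", {
  cfg <- flat_config(n_alines = 32L, n_depth_px = 64L, surface_depth_px = 8L)
  s1 <- generate_stack(cfg, n_frames = 3, seed = 7)
  s2 <- generate_stack(cfg, n_frames = 3, seed = 7)
  expect_identical(s1$frames, s2$frames)
  one <- generate_stack(cfg, n_frames = 1, seed = 7)
  expect_equal(one$frames[, , 1], generate_bscan(cfg, derive_seed(7, 1)))
  expect_error(generate_stack(cfg, n_frames = 0, seed = 1), "n_frames")
  # full-size geometry: 813 x 750 (width x height) frames
  big <- generate_stack(leaf_preset("green"), n_frames = 2, seed = 1)
  expect_equal(dim(big$frames), c(750L, 813L, 2L))
})

test_that("labeled datasets keep the requested composition", {
  ds <- generate_labeled_dataset(0, 0, 1, seed = 3, n_frames = 1,
                                 n_alines = 32L, n_depth_px = 64L)
  expect_length(ds, 1)
  expect_equal(dataset_labels(ds), "red")
  ds2 <- generate_labeled_dataset(4, 3, 5, seed = 3, n_frames = 1,
                                  n_alines = 32L, n_depth_px = 64L)
  expect_equal(as.vector(table(dataset_labels(ds2))[c("green", "yellow", "red")]),
               c(4L, 3L, 5L))
  # per-sample jitter: attenuations vary around the preset mean
  atts <- vapply(ds2, function(s) s$config$attenuation_db_per_um, numeric(1))
  expect_gt(stats::sd(atts[dataset_labels(ds2) == "green"]), 0)
})

test_that("averaged speckled A-lines are log-linear at the configured slope", {
  cfg <- leaf_preset("green", n_alines = 256L, n_depth_px = 256L, seed = 2)
  stack <- generate_stack(cfg, n_frames = 200, seed = 1)
  fit <- estimate_attenuation(stack)
  expect_lt(abs(fit$slope_db_per_um - cfg$attenuation_db_per_um), 0.05)
  expect_gt(fit$r_squared, 0.99)
})

test_that("peak separability matches the stage anatomy", {
  sub_surface_peaks <- function(stage, seed) {
    cfg <- leaf_preset(stage, n_alines = 256L, n_depth_px = 256L, seed = seed)
    stack <- generate_stack(cfg, n_frames = 200, seed = seed + 500)
    al <- extract_averaged_aline(average_frames(stack), stack$axial_pitch_um)
    db <- to_db(normalize_aline(al), floor = .Machine$double.xmin)
    pk <- detect_peaks(db)
    sum(pk$peaks$depth_px > pk$surface_index)
  }
  expect_gte(sub_surface_peaks("green", 1), 2)
  expect_equal(sub_surface_peaks("yellow", 2), 1)
  expect_equal(sub_surface_peaks("red", 3), 1)
})

test_that("speckle marginal is unit-mean exponential", {
  cfg <- flat_config(attenuation = -0.3, contrast = 0.5, n_alines = 320L,
                     n_depth_px = 330L, surface_depth_px = 10L, seed = 9L)
  m <- generate_bscan(within_none(cfg), seed = 1)
  b <- generate_bscan(cfg, seed = 123)
  tissue <- cfg$surface_depth_px:cfg$n_depth_px
  ratio <- as.vector(b[tissue, ] / m[tissue, ])
  expect_gte(length(ratio), 1e5)
  ks <- suppressWarnings(stats::ks.test(ratio, "pexp", 1))
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(ratio), 1, tolerance = 0.02)
})
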
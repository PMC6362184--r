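test_that("frame averaging is an arithmetic mean with the expected noise gain", {
  frame <- matrix(runif(32 * 16), 32, 16)
  same <- bscan_stack(array(frame, c(32, 16, 3)), 2.46, 2.665)
  expect_equal(average_frames(same), frame)
  two <- bscan_stack(array(c(frame * 0, frame * 4), c(32, 16, 2)), 2.46, 2.665)
  expect_equal(average_frames(two), frame * 2)
  # speckle: SD of a 200-frame average ~ per-frame SD / sqrt(200)
  cfg <- flat_config(attenuation = -0.2, n_alines = 32L, n_depth_px = 64L,
                     surface_depth_px = 8L)
  stack <- generate_stack(cfg, n_frames = 200, seed = 4)
  m <- generate_bscan(within_none(cfg), seed = 1)
  tissue <- cfg$surface_depth_px:cfg$n_depth_px
  z <- (average_frames(stack)[tissue, ] - m[tissue, ]) / m[tissue, ]
  expect_equal(stats::sd(as.vector(z)), 1 / sqrt(200), tolerance = 0.1)
})

test_that("lateral averaging selects and averages the requested columns", {
  img <- matrix(rnorm(50 * 20)^2, 50, 20)
  expect_equal(extract_averaged_aline(img, 2.665, count = 20L)$values,
               rowMeans(img))
  expect_equal(extract_averaged_aline(img, 2.665, start_aline = 3L,
                                      count = 1L)$values, img[, 3])
  const <- matrix(4.2, 10, 8)
  expect_equal(extract_averaged_aline(const, 2.665, count = 4L)$values,
               rep(4.2, 10))
  expect_error(extract_averaged_aline(img, 2.665, start_aline = 15L,
                                      count = 10L), "outside")
  al <- extract_averaged_aline(img, 2.665, count = 10L)
  expect_equal(al$provenance$start_aline, 6L)  # centered window
})

test_that("smoothing is a length-preserving moving average", {
  al <- aline(c(rep(0, 10), 7, rep(0, 10)), "linear", 2.665)
  expect_equal(smooth_aline(al, 1L)$values, al$values)
  sm <- smooth_aline(al, 5L)
  expect_equal(sm$values[9:13], rep(7 / 5, 5))
  expect_equal(sum(sm$values), sum(al$values))
  const <- aline(rep(3, 25), "linear", 2.665)
  expect_equal(smooth_aline(const, 7L)$values, const$values)
  expect_error(smooth_aline(al, 4L), "odd")
  expect_error(smooth_aline(al, -3), "odd")
})

test_that("normalization rescales to unit maximum and is idempotent", {
  al <- aline(c(1, 4, 2), "linear", 2.665)
  norm <- normalize_aline(al)
  expect_equal(max(norm$values), 1)
  expect_equal(norm$values, al$values / 4)
  expect_equal(normalize_aline(norm)$values, norm$values)
  expect_true(norm$normalized)
  expect_error(normalize_aline(aline(c(0, 0), "linear", 1)), "all-zero")
  for (s in 1:20) {
    x <- aline(withr::with_seed(s, runif(80) + 0.01), "linear", 2.665)
    expect_equal(max(normalize_aline(smooth_aline(x, 5L))$values), 1)
  }
})

test_that("dB conversion follows the 10 log10 intensity convention", {
  expect_equal(to_db(aline(c(1, 10, 100), "linear", 1))$values, c(0, 10, 20))
  z <- seq(0, 50, by = 1)
  al <- aline(10^(-z / 10), "linear", 1)
  db <- to_db(al)
  expect_equal(diff(db$values), rep(-1, 50))
  expect_error(to_db(aline(c(1, 0), "linear", 1)), "non-positive")
  expect_equal(to_db(aline(c(1, 0), "linear", 1), floor = 1e-10)$values,
               c(0, -100))
})

test_that("peak detection finds constructed peaks and honours the boundary rule", {
  z <- seq(0, 300, by = 2.665)
  prof <- exp(-(z - 50)^2 / 50) + 0.6 * exp(-(z - 150)^2 / 50)
  pk <- detect_peaks(aline(prof / max(prof), "linear", 2.665,
                           normalized = TRUE))
  expect_equal(nrow(pk$peaks), 2)
  expect_equal(pk$peaks$depth_um, c(50, 150), tolerance = 2.665)
  expect_equal(pk$surface_index, pk$peaks$depth_px[1])
  # monotone ramp: endpoints are not eligible -> empty set, flagged
  ramp <- detect_peaks(aline(seq(0, 1, length.out = 40), "linear", 2.665))
  expect_true(ramp$empty)
  expect_equal(nrow(ramp$peaks), 0)
  expect_equal(ramp$surface_index, 40L)  # global maximum still reported
})

test_that("layer thickness converts peak separation to micrometres", {
  peaks <- structure(list(
    peaks = data.frame(depth_px = c(100L, 150L),
                       depth_um = c(99, 149) * 2.665,
                       height = c(1, 0.5), prominence = c(1, 0.5)),
    surface_index = 100L, axial_pitch_um = 2.665, empty = FALSE),
    class = "peak_set")
  expect_equal(layer_thickness(peaks, 1, 2), 50 * 2.665)
  expect_error(layer_thickness(peaks, 1, 1), "i < j")
  expect_error(layer_thickness(peaks, 1, 3), "indices")
  # phantom with epidermis top at 40 um and palisade top at 120 um
  cfg <- phantom_config("toy", list(
    layer_spec("cuticle", 0, 20, interface_reflectivity = 40),
    layer_spec("epidermis", 40, 80, interface_reflectivity = 40),
    layer_spec("palisade", 120, 300, interface_reflectivity = 40)),
    attenuation_db_per_um = -0.5, surface_depth_px = 20L,
    n_alines = 64L, n_depth_px = 200L)
  cfg$speckle <- "none"
  al <- extract_averaged_aline(average_frames(generate_stack(cfg, 1, 1)),
                               cfg$axial_pitch_um, count = 64L)
  pk <- detect_peaks(to_db(normalize_aline(al), floor = .Machine$double.xmin))
  sub <- pk$peaks[pk$peaks$depth_px > pk$surface_index, ]
  expect_equal(nrow(sub), 2)
  idx <- match(sub$depth_px, pk$peaks$depth_px)
  expect_equal(layer_thickness(pk, idx[1], idx[2]), 80, tolerance = 3)
})

test_that("attenuation fitting matches the normal-equation OLS oracle", {
  pitch <- 2.665
  z <- (0:199) * pitch
  exact <- aline(-1.0 * z + 5, "dB", pitch)
  fit <- fit_attenuation(exact, surface_index = 1L, offset_px = 10L,
                         window_um = 320)
  expect_equal(fit$slope_db_per_um, -1.0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$n_points, round(320 / pitch))
  flat <- fit_attenuation(aline(rep(3, 200), "dB", pitch), 1L)
  expect_equal(flat$slope_db_per_um, 0)
  # quadratic and random profiles against brute-force normal equations
  for (s in 1:100) {
    prof <- withr::with_seed(s, {
      a <- rnorm(3)
      a[1] + a[2] * z / 100 + a[3] * (z / 100)^2 + rnorm(200, sd = 0.2)
    })
    fit <- fit_attenuation(aline(prof, "dB", pitch), surface_index = 5L)
    rows <- fit$window["start_px"]:(fit$window["end_px"] - 1L)
    oracle <- oracle_ols((rows - 1) * pitch, prof[rows])
    expect_equal(fit$slope_db_per_um, unname(oracle["slope"]),
                 tolerance = 1e-9)
    expect_equal(fit$intercept_db, unname(oracle["intercept"]),
                 tolerance = 1e-9)
  }
  expect_error(fit_attenuation(exact, surface_index = 150L), "exceeds")
})

test_that("the noiseless pipeline recovers the configured slope exactly", {
  cfg <- flat_config(attenuation = -0.9)
  cfg$speckle <- "none"
  stack <- generate_stack(cfg, 1, 1)
  fit <- estimate_attenuation(stack)
  expect_lt(abs(fit$slope_db_per_um - -0.9), 1e-3)
  # global intensity scaling leaves the slope unchanged, shifts the intercept
  scaled <- stack
  scaled$frames <- stack$frames * 37
  fit2 <- estimate_attenuation(scaled)
  expect_equal(fit2$slope_db_per_um, fit$slope_db_per_um, tolerance = 1e-12)
  expect_equal(fit2$intercept_db, fit$intercept_db, tolerance = 1e-9)
})

test_that("surface shifts translate the fit window without changing the slope", {
  slopes <- sapply(c(20L, 27L), function(sd_px) {
    cfg <- flat_config(attenuation = -0.7, surface_depth_px = sd_px)
    cfg$speckle <- "none"
    stack <- generate_stack(cfg, 1, 1)
    al <- extract_averaged_aline(average_frames(stack), cfg$axial_pitch_um,
                                 count = 64L)
    pk <- detect_peaks(normalize_aline(smooth_aline(al)))
    c(surface = pk$surface_index,
      slope = estimate_attenuation(stack)$slope_db_per_um)
  })
  expect_equal(unname(slopes["surface", 2] - slopes["surface", 1]), 7)
  expect_equal(unname(slopes["slope", 1]), unname(slopes["slope", 2]),
               tolerance = 1e-9)
})

test_that("estimator bias is small and replicate scatter shrinks with averaging", {
  cfg <- leaf_preset("yellow", n_alines = 128L, n_depth_px = 192L)
  slopes_by_frames <- lapply(c(10L, 50L, 200L), function(nf) {
    sapply(1:8, function(r) {
      cfg$seed <- 1000L + r
      estimate_attenuation(
        generate_stack(cfg, nf, seed = r * 17L))$slope_db_per_um
    })
  })
  sds <- vapply(slopes_by_frames, stats::sd, numeric(1))
  expect_true(all(diff(sds) < 0))   # SD decreases with n_frames
  expect_lt(abs(mean(slopes_by_frames[[3]]) - cfg$attenuation_db_per_um), 0.03)
})

test_that("en face slices pick the depth plane nearest the requested depth", {
  cfg <- flat_config(attenuation = -0.4, n_alines = 24L, n_depth_px = 96L,
                     surface_depth_px = 10L)
  cfg$speckle <- "none"
  stack <- generate_stack(cfg, 5, 1)
  expect_equal(enface_slice(stack, 0), stack$frames[1, , ])
  expect_equal(enface_slice(stack, 49 * cfg$axial_pitch_um),
               stack$frames[50, , ])
  expect_equal(dim(enface_slice(stack, 100)), c(24L, 5L))
  expect_error(enface_slice(stack, 1e5), "outside")
  # surface interface plane is brighter than a plane 50 um deeper
  surf_um <- (cfg$surface_depth_px - 1) * cfg$axial_pitch_um
  expect_gt(mean(enface_slice(stack, surf_um)),
            mean(enface_slice(stack, surf_um + 50)))
})
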
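test_that("noiseless plateau geometry passes straight through", {
  tr <- centriole_truth("side", tubulin_length_nm = 400)
  g <- generate_profile(tr, noiseless_model(pixel_size_nm = 10),
                        "longitudinal")
  v <- g$profile$intensities$tubulin
  expect_identical(sum(v > 0), 40L)
  e <- detect_extent(g$profile, "tubulin")
  expect_equal(e$start_nm, 0)
  expect_equal(e$end_nm, 400)
  expect_s3_class(g$truth, "centriole_truth")
})

test_that("profile generation is seed-deterministic, bytewise", {
  tr <- centriole_truth("side")
  mod <- imaging_model(rng_seed = 7L)
  p1 <- generate_profile(tr, mod, "longitudinal")$profile
  p2 <- generate_profile(tr, mod, "longitudinal")$profile
  expect_identical(p1, p2)
  mod2 <- imaging_model(rng_seed = 8L)
  p3 <- generate_profile(tr, mod2, "longitudinal")$profile
  expect_false(identical(p1$intensities, p3$intensities))
})

test_that("half-max extent of the mean of noisy blurred profiles recovers the plateau", {
  tr <- centriole_truth("side", tubulin_length_nm = 390,
                        marker_model = "absent")
  mean_tub <- NULL
  pos <- NULL
  for (i in 1:100) {
    mod <- imaging_model(pixel_size_nm = 10, psf_sigma_nm = 60,
                         photon_scale = 2000, read_noise_sd = 0,
                         background_offset = 0, rng_seed = i)
    p <- generate_profile(tr, mod, "longitudinal")$profile
    mean_tub <- if (is.null(mean_tub)) p$intensities$tubulin else
      mean_tub + p$intensities$tubulin
    pos <- p$positions_nm
  }
  mean_tub <- mean_tub / 100
  ext <- oracle_halfmax_extent(pos, mean_tub)
  measured <- ext["end"] - ext["start"]
  expect_lt(abs(measured - 390), 5)
  # and the independent discrete-convolution oracle agrees on the ideal
  conv <- oracle_convolved_plateau_extent(390, 60)
  expect_lt(abs((conv["end"] - conv["start"]) - 390), 1)
})

test_that("rendered side view forms two parallel bars at the wall diameter", {
  tr <- centriole_truth("side", tubulin_length_nm = 1500,
                        tubulin_diameter_nm = 960, wall_thickness_nm = 100,
                        marker_model = "absent")
  mod <- noiseless_model(pixel_size_nm = 50)
  g <- generate_centriole_image(tr, mod, canvas_px = c(64L, 64L),
                                pose = list(center_px = c(32, 32),
                                            angle_deg = 0))
  tub <- g$image$channels$tubulin
  # columns through the structure show two bands; their row centroids are
  # separated by the wall diameter within one pixel
  mid_col <- tub[, 32]
  rows <- which(mid_col > 0)
  top <- rows[rows < 32]
  bot <- rows[rows > 32]
  expect_gt(length(top), 0)
  expect_gt(length(bot), 0)
  sep_px <- weighted.mean(bot, mid_col[bot]) - weighted.mean(top, mid_col[top])
  expect_lt(abs(sep_px * 50 - 960), 50)
  # marker absent: channel contains no signal at all without noise
  expect_true(all(g$image$channels$marker == 0))
})

test_that("rendered bottom view has ring peaks at the marker/tubulin diameters", {
  tr <- centriole_truth("bottom", marker_model = "proximal_ring")
  mod <- noiseless_model(pixel_size_nm = 50)
  g <- generate_centriole_image(tr, mod, canvas_px = c(72L, 72L),
                                pose = list(center_px = c(36, 36),
                                            angle_deg = 0))
  img <- g$image
  prof <- extract_line_profile(img, c(6, 36), c(66, 36), width_px = 1L)
  m <- measure_bottom_view(prof, mode = "peak_to_peak")
  expect_lt(abs(m$diameter_nm[["tubulin"]] - tr$tubulin_diameter_nm), 50)
  expect_lt(abs(m$diameter_nm[["marker"]] - tr$marker_diameter_nm), 50)
})

test_that("structure overflowing the canvas is refused", {
  tr <- centriole_truth("side", tubulin_length_nm = 5000)
  expect_error(
    generate_centriole_image(tr, noiseless_model(pixel_size_nm = 50),
                             canvas_px = c(32L, 32L),
                             pose = list(center_px = c(16, 16),
                                         angle_deg = 0)),
    "exceeds the canvas")
})

test_that("image rendering is seed-deterministic", {
  tr <- centriole_truth("bottom")
  mod <- imaging_model(pixel_size_nm = 50, rng_seed = 7L)
  g1 <- generate_centriole_image(tr, mod, canvas_px = c(72L, 72L))
  g2 <- generate_centriole_image(tr, mod, canvas_px = c(72L, 72L))
  expect_identical(g1$image, g2$image)
})

test_that("noise-free profiles integrate to intensity_scale x structure size", {
  tr <- centriole_truth("side", tubulin_length_nm = 400,
                        intensity_scale = c(tubulin = 2.5, marker = 1))
  for (sigma in c(0, 40)) {
    g <- generate_profile(tr, noiseless_model(pixel_size_nm = 10,
                                              psf_sigma_nm = sigma),
                          "longitudinal")
    integral <- sum(g$profile$intensities$tubulin) * 10
    expect_equal(integral, 2.5 * 400,
                 tolerance = if (sigma == 0) 1e-9 else 1e-3)
  }
})

test_that("blur never shrinks the half-max extent of the mean profile", {
  tr <- centriole_truth("side", tubulin_length_nm = 300,
                        marker_model = "absent")
  widths <- vapply(c(0, 20, 60, 120, 200), function(sigma) {
    g <- generate_profile(tr, noiseless_model(pixel_size_nm = 10,
                                              psf_sigma_nm = sigma),
                          "longitudinal")
    e <- detect_extent(g$profile, "tubulin")
    e$end_nm - e$start_nm
  }, 1.0)
  expect_true(all(diff(widths) >= -1e-6))
})

test_that("growth series respects the onset rule and reproduces under seed", {
  gs <- generate_growth_series(100, c(40, 400), 120, imaging_model(),
                               seed = 11L)
  below <- gs$series$length_nm < 120
  models <- vapply(gs$truths, function(t) t$marker_model, "")
  expect_true(all(models[below] == "absent"))
  expect_true(all(!gs$series$present[below]))
  gs2 <- generate_growth_series(100, c(40, 400), 120, imaging_model(),
                                seed = 11L)
  expect_identical(gs, gs2)
})

test_that("growth-series presence split matches an independent recount", {
  gs <- generate_growth_series(93, c(40, 400), 120, imaging_model(),
                               seed = 5L)
  # brute-force recount straight from the drawn lengths
  n_present <- sum(gs$series$length_nm >= 120)
  expect_identical(sum(gs$series$present), n_present)
  expect_identical(sum(!gs$series$present), 93L - n_present)
  # marker extent follows the linear growth rule
  pres <- gs$series[gs$series$present, ]
  expect_equal(pres$marker_length_nm,
               pmin(107.6, 0.5 * (pres$length_nm - 120)))
})

test_that("onset outside the length range warns but still generates", {
  expect_warning(
    gs <- generate_growth_series(10, c(40, 100), 120, imaging_model(),
                                 seed = 1L),
    "outside")
  expect_true(all(!gs$series$present))
})

test_that("cyst-count sampler matches the mixture it samples from", {
  # f = 0: 8-cell-stage failure only, every cell has one centriole
  c0 <- generate_cyst_counts(500, 0, seed = 3L)
  expect_identical(unname(c0[["1C"]]), 500L)
  # seeded determinism
  expect_identical(generate_cyst_counts(200, 0.3, seed = 9L),
                   generate_cyst_counts(200, 0.3, seed = 9L))
  # f = 1: empirical 0C fraction converges to the predicted 0.5
  c1 <- generate_cyst_counts(10000, 1, seed = 4L)
  p0 <- c1[["0C"]] / 10000
  se <- sqrt(0.5 * 0.5 / 10000)
  expect_lt(abs(p0 - 0.5), 3 * se)
})
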
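test_that("expansion calibration is the disk/punch ratio", {
  expect_equal(calibrate_expansion(16)$factor, 4)
  expect_equal(calibrate_expansion(4)$factor, 1)
  expect_equal(calibrate_expansion(17.2)$factor, 4.3)
  expect_error(calibrate_expansion(-1), "positive")
  expect_equal(calibrate_expansion(16)$em_reference_nm, c(200, 12))
})

test_that("expansion correction divides all nm fields once and only once", {
  m <- fake_side_measurement(c(100, 580), c(100, 200))
  cal <- calibrate_expansion(16)
  mc <- correct_measurement(m, cal)
  expect_equal(mc$length_nm[["tubulin"]], 120)
  expect_equal(mc$extents$marker$start_nm, 25)
  expect_equal(mc$space, "corrected")
  expect_equal(mc$expansion_factor, 4)
  expect_error(correct_measurement(mc, cal), "already")
  # factor 1 changes nothing but the flag
  m1 <- correct_measurement(m, calibrate_expansion(4))
  expect_equal(m1$length_nm, m$length_nm)
  expect_equal(m1$space, "corrected")
})

test_that("noiseless side view measures the true length within a resampled step", {
  tr <- centriole_truth("side", tubulin_length_nm = 390,
                        marker_model = "absent")
  g <- generate_profile(tr, noiseless_model(pixel_size_nm = 10),
                        "longitudinal")
  m <- measure_side_view(g$profile, id = "c1")
  expect_lt(abs(m$length_nm[["tubulin"]] - 390), 10 / 3)
  expect_equal(m$space, "expanded")
})

test_that("a flat marker channel is recorded absent, tubulin measured normally", {
  tr <- centriole_truth("side", tubulin_length_nm = 400,
                        marker_model = "absent")
  g <- generate_profile(tr, noiseless_model(pixel_size_nm = 10),
                        "longitudinal")
  m <- measure_side_view(g$profile)
  expect_true(is_no_signal(m$extents$marker))
  expect_true(is.na(m$length_nm[["marker"]]))
  expect_false(is.na(m$length_nm[["tubulin"]]))
})

test_that("doubling all intensities leaves every extent unchanged", {
  tr <- centriole_truth("side", tubulin_length_nm = 500)
  g <- generate_profile(tr, noiseless_model(pixel_size_nm = 10,
                                            psf_sigma_nm = 40),
                        "longitudinal")
  p <- g$profile
  p2 <- line_profile(p$positions_nm, lapply(p$intensities, `*`, 2))
  m1 <- measure_side_view(p)
  m2 <- measure_side_view(p2)
  expect_equal(m1$length_nm, m2$length_nm, tolerance = 1e-9)
  expect_equal(m1$extents$marker$start_nm, m2$extents$marker$start_nm,
               tolerance = 1e-9)
})

test_that("missing tubulin signal is an error", {
  p <- line_profile(0:9, list(tubulin = rep(0, 10),
                              marker = c(0, 0, 1, 4, 9, 9, 4, 1, 0, 0)))
  expect_error(measure_side_view(p), "no tubulin signal")
})

test_that("noiseless ring diameter is recovered peak-to-peak", {
  tr <- centriole_truth("bottom", tubulin_diameter_nm = 240,
                        wall_thickness_nm = 25,
                        marker_model = "proximal_ring",
                        marker_diameter_nm = 240)
  g <- generate_profile(tr, noiseless_model(pixel_size_nm = 10,
                                            psf_sigma_nm = 15),
                        "radial")
  m <- measure_bottom_view(g$profile, mode = "peak_to_peak")
  expect_lt(abs(m$diameter_nm[["tubulin"]] - 240), 10 / 3)
  expect_equal(m$diameter_mode, "peak_to_peak")
  mo <- measure_bottom_view(g$profile, mode = "outer_half_max")
  expect_gte(mo$diameter_nm[["tubulin"]], m$diameter_nm[["tubulin"]])
})

test_that("single-peaked profiles are rejected as rings", {
  x <- 0:20
  v <- exp(-(x - 10)^2 / 8)
  p <- line_profile(x, list(tubulin = v))
  expect_error(measure_bottom_view(p), "fewer than two peaks")
})

test_that("relative positions are tubulin-referenced and shift-invariant", {
  m <- fake_side_measurement(c(100, 500), c(100, 200))
  r <- relative_position(m)
  expect_equal(r$marker_start_rel_nm, 0)
  expect_equal(r$marker_end_rel_nm, 100)
  expect_true(r$present)
  # translation of both extents leaves the record unchanged
  m2 <- fake_side_measurement(c(137, 537), c(137, 237))
  r2 <- relative_position(m2)
  expect_equal(r2$marker_start_rel_nm, r$marker_start_rel_nm)
  expect_equal(r2$marker_end_rel_nm, r$marker_end_rel_nm)
  # marker capping below the wall start yields a negative relative start
  m3 <- fake_side_measurement(c(100, 500), c(80, 190))
  r3 <- relative_position(m3)
  expect_equal(r3$marker_start_rel_nm, -20)
  expect_equal(r3$marker_end_rel_nm, 90)
  # absent marker flagged, not zeroed
  m4 <- fake_side_measurement(c(100, 500), NULL)
  expect_false(relative_position(m4)$present)
  # bottom views are refused
  m5 <- m
  m5$view <- "bottom"
  expect_error(relative_position(m5), "side views")
})

test_that("position summaries use the sample sd and ignore record order", {
  recs <- rbind(relative_position(fake_side_measurement(c(0, 400), c(0, 100))),
                relative_position(fake_side_measurement(c(0, 420), c(0, 120))))
  s <- summarize_positions(recs)
  ps <- s$position_stats
  expect_equal(ps$mean[ps$quantity == "marker_start_rel_nm"], 0)
  expect_equal(ps$sd[ps$quantity == "marker_start_rel_nm"], 0)
  expect_equal(ps$mean[ps$quantity == "marker_end_rel_nm"], 110)
  expect_equal(ps$sd[ps$quantity == "marker_end_rel_nm"], sd(c(100, 120)))
  # permutation invariance
  s2 <- summarize_positions(recs[2:1, ])
  expect_equal(s2$position_stats, s$position_stats)
  # single record: sd 0 with the flag set
  s1 <- summarize_positions(recs[1, ])
  expect_true(all(s1$position_stats$single_record))
  expect_equal(s1$position_stats$sd, c(0, 0))
  # no present records is an error
  none <- relative_position(fake_side_measurement(c(0, 400), NULL))
  expect_error(summarize_positions(none), "no records")
})

test_that("binned growth curves average within bins", {
  recs <- do.call(rbind, lapply(1:8, function(i)
    relative_position(fake_side_measurement(c(0, 100 * i),
                                            c(0, 10 * i)))))
  recs$id <- seq_len(nrow(recs))
  s <- summarize_positions(recs, bin_width_nm = 250)
  expect_false(is.null(s$binned))
  expect_equal(sum(s$binned$n), 8)
  expect_true(all(diff(s$growth_curve$tubulin_length_nm) >= 0))
})

test_that("measuring then correcting equals correcting the geometry first", {
  # a truth rendered at factor f and measured, then divided by f, matches
  # the same biological truth rendered at factor 1 (pixels scale with f)
  f <- 4
  L_bio <- 390
  tr_f <- centriole_truth("side", tubulin_length_nm = L_bio * f,
                          marker_model = "absent")
  tr_1 <- centriole_truth("side", tubulin_length_nm = L_bio,
                          marker_model = "absent")
  m_f <- measure_side_view(generate_profile(
    tr_f, noiseless_model(pixel_size_nm = 10 * f, psf_sigma_nm = 15 * f),
    "longitudinal")$profile)
  m_1 <- measure_side_view(generate_profile(
    tr_1, noiseless_model(pixel_size_nm = 10, psf_sigma_nm = 15),
    "longitudinal")$profile)
  corrected <- correct_measurement(m_f, calibrate_expansion(4 * f))
  expect_equal(corrected$length_nm[["tubulin"]], m_1$length_nm[["tubulin"]],
               tolerance = 1e-9)
})

test_that("corrected diameter of a factor-4 synthetic centriole sits in the EM band", {
  cal <- calibrate_expansion(16)
  tr <- centriole_truth("bottom", tubulin_diameter_nm = 200 * 4,
                        marker_model = "absent")
  ds <- vapply(1:10, function(i) {
    g <- generate_profile(tr, snr10_model(i), "radial")
    m <- correct_measurement(measure_bottom_view(g$profile), cal)
    m$diameter_nm[["tubulin"]]
  }, 1.0)
  band <- cal$em_reference_nm
  expect_lt(abs(mean(ds) - band[1]), band[2])
})
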
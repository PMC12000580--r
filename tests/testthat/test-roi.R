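make_spot_image <- function(spot_value = 100, control_value = 50,
                            offset = 0, dim = 32L, half = 2L) {
  tgt <- matrix(offset, dim, dim)
  ctl <- matrix(offset, dim, dim)
  mid <- dim %/% 2L
  idx <- (mid - half):(mid + half)
  tgt[idx, idx] <- spot_value + offset
  ctl[idx, idx] <- control_value + offset
  image_plane(list(target = tgt, control = ctl), pixel_size_nm = 70,
              expansion_factor = 4)
}

test_that("Otsu segmentation recovers an isolated bright square exactly", {
  img <- make_spot_image(spot_value = 100, dim = 32L, half = 2L)
  mask <- segment_roi(img, "target", c(16, 16), method = "otsu")
  expect_equal(sum(mask), 25)
  expect_true(all(which(mask) == which(img$channels$target == 100)))
})

test_that("fixed thresholds above the maximum give an empty-ROI error", {
  img <- make_spot_image()
  expect_error(segment_roi(img, "target", c(16, 16), method = "fixed",
                           fixed_value = 1e6), "empty ROI")
  expect_error(segment_roi(img, "target", c(16, 16), method = "fixed"),
               "fixed_value")
  # seed below threshold is also an empty ROI
  expect_error(segment_roi(img, "target", c(2, 2), method = "fixed",
                           fixed_value = 50), "empty ROI")
})

test_that("segmentation keeps only the component containing the seed", {
  m <- matrix(0, 40, 40)
  m[10:12, 10:12] <- 100  # spot A
  m[30:32, 30:32] <- 100  # spot B
  img <- image_plane(list(ch = m), pixel_size_nm = 70, expansion_factor = 4)
  mask <- segment_roi(img, "ch", c(11, 11), method = "fixed",
                      fixed_value = 50)
  expect_equal(sum(mask), 9)
  expect_true(all(mask[10:12, 10:12]))
  expect_false(any(mask[30:32, 30:32]))
})

test_that("square ROIs have the right area and stay inside the image", {
  mask <- square_roi(c(10, 10), 3L, c(32L, 32L))
  expect_equal(sum(mask), 49)
  # the filled region is a centred square: invariant under 90-degree
  # rotation about the seed, i.e. mask[cy + dy, cx + dx] == mask[cy + dx,
  # cx - dy] for all offsets
  offs <- -4:4
  for (dy in offs) for (dx in offs)
    expect_identical(mask[10 + dy, 10 + dx], mask[10 + dx, 10 - dy])
  expect_error(square_roi(c(1, 1), 1L, c(32L, 32L)), "exits the image")
})

test_that("net intensity is integrated minus background times area", {
  # uniform 10 over a 100-px mask on background 2: net = 100 * (10 - 2)
  m <- matrix(2, 30, 30)
  m[11:20, 11:20] <- 10
  img <- image_plane(list(ch = m), pixel_size_nm = 70, expansion_factor = 4)
  mask <- matrix(FALSE, 30, 30)
  mask[11:20, 11:20] <- TRUE
  q <- quantify_roi(img, "ch", mask, background = "annulus")
  expect_equal(q$area_px, 100)
  expect_equal(q$background_per_px, 2)
  expect_equal(q$net_intensity, 800)
  qg <- quantify_roi(img, "ch", mask, background = "global_percentile")
  expect_equal(qg$net_intensity, 800)
  expect_error(quantify_roi(img, "ch", mask & FALSE), "empty mask")
})

test_that("control normalization divides by the control net on the same mask", {
  m <- matrix(2, 30, 30); m[11:20, 11:20] <- 10
  ctl <- matrix(1, 30, 30); ctl[11:20, 11:20] <- 5
  img <- image_plane(list(tgt = m, bld10 = ctl), pixel_size_nm = 70,
                     expansion_factor = 4)
  mask <- matrix(FALSE, 30, 30); mask[11:20, 11:20] <- TRUE
  q <- quantify_roi(img, "tgt", mask, control_channel = "bld10")
  expect_equal(q$control_net_intensity, 400)
  expect_equal(q$normalized, 2.0)
  expect_error(quantify_roi(img, "tgt", mask, control_channel = "nope"),
               "control channel")
})

test_that("net intensity is linear and normalization is scale-free", {
  m <- matrix(2, 30, 30); m[11:20, 11:20] <- 10
  ctl <- m / 2
  mask <- matrix(FALSE, 30, 30); mask[11:20, 11:20] <- TRUE
  img <- image_plane(list(tgt = m, ctl = ctl), pixel_size_nm = 70,
                     expansion_factor = 4)
  img3 <- image_plane(list(tgt = 3 * m, ctl = 3 * ctl), pixel_size_nm = 70,
                      expansion_factor = 4)
  q1 <- quantify_roi(img, "tgt", mask, control_channel = "ctl")
  q3 <- quantify_roi(img3, "tgt", mask, control_channel = "ctl")
  expect_equal(q3$net_intensity, 3 * q1$net_intensity)
  expect_equal(q3$normalized, q1$normalized, tolerance = 1e-12)
})

test_that("Poisson spots are quantified without bias at the expected precision", {
  # Gaussian spot holding S photons in total on a constant camera offset
  S <- 10000
  sigma <- 2
  n <- 41L
  xy <- seq_len(n) - 21
  kern <- outer(dnorm(xy, sd = sigma), dnorm(xy, sd = sigma))
  ideal <- S * kern / sum(kern)
  mask <- matrix(abs(xy) <= 8, n, n, byrow = TRUE) &
    matrix(abs(xy) <= 8, n, n)
  withr::with_seed(101, {
    nets <- replicate(100, {
      noisy <- matrix(rpois(n * n, ideal), n, n) + 3
      img <- image_plane(list(ch = noisy), pixel_size_nm = 70,
                         expansion_factor = 4)
      quantify_roi(img, "ch", mask, background = "annulus")$net_intensity
    })
    # CLT bound on the mean of 100 realizations, each with sd ~ sqrt(S)
    expect_lt(abs(mean(nets) - S), 3 * sqrt(S) / sqrt(100) * 1.2)
  })
})

test_that("batch quantification keys stages and de-anonymizes exactly", {
  genotypes <- rep(c("control", "mutant"), each = 30)
  stages <- rep(rep(c("SG", "earlySC", "lateSC"), each = 10), 2)
  images <- list()
  ann <- data.frame(image = paste0("img", 1:60), x = 16, y = 16,
                    stage = stages, genotype = genotypes,
                    roi_kind = "threshold", half_width_px = 3L)
  for (i in 1:60) {
    val <- if (genotypes[i] == "mutant") 60 else 100
    images[[paste0("img", i)]] <- make_spot_image(spot_value = val,
                                                  control_value = 50)
  }
  res <- batch_quantify(ann, images, channel = "target",
                        control_channel = "control")
  expect_equal(nrow(res$table), 60)
  expect_null(res$key)
  expect_equal(sort(unique(res$table$stage)), sort(unique(stages)))
  # anonymized: genotype only in the key, and the key restores it exactly
  anon <- batch_quantify(ann, images, channel = "target",
                         control_channel = "control", anonymize = TRUE,
                         key_seed = 3L)
  expect_false("genotype" %in% names(anon$table))
  restored <- anon$key$genotype[match(anon$table$anon_id, anon$key$anon_id)]
  expect_identical(restored, genotypes)
  # missing images are refused; small stages warn
  expect_error(batch_quantify(ann[1:2, ], images[0], "target"),
               "missing images")
  expect_warning(batch_quantify(ann[1:5, ], images, "target"),
                 "fewer than")
})

test_that("square ROI batch path quantifies with the requested geometry", {
  img <- make_spot_image(spot_value = 80, half = 3L)
  ann <- data.frame(image = "a", x = 16, y = 16, stage = "SG",
                    genotype = "control", roi_kind = "square",
                    half_width_px = 3L)
  expect_warning(res <- batch_quantify(ann, list(a = img), "target"),
                 "fewer than")
  expect_equal(res$table$area_px, 49)
  expect_equal(res$table$roi_kind, "square")
})
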
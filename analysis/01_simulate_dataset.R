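#!/usr/bin/env Rscript
# Step 1: build the synthetic expanded-centriole dataset with known ground
# truth. Renders mature-centriole side and bottom views at a gel expansion
# factor of 4 (geometry: tubulin wall 389.1 x 241.7 nm, proximal marker cap
# 107.6 x 240.1 nm, biological values), writes the TIFF images with their
# calibration sidecars under scratch/images/, and the ground-truth and
# line-scan annotation tables under results/.
#
# Run from the repository root: Rscript analysis/01_simulate_dataset.R

suppressMessages(library(uexm))

seed_base <- 100L
n_side <- 25L
n_bottom <- 25L
img_dir <- "scratch/images"
dir.create(img_dir, showWarnings = FALSE, recursive = TRUE)
dir.create("results", showWarnings = FALSE)

model_for <- function(seed) imaging_model(
  pixel_size_nm = 70, psf_sigma_nm = 80, photon_scale = 400,
  read_noise_sd = 0.05, background_offset = 0.2, expansion_factor = 4,
  rng_seed = seed)

truth_rows <- list()
annotations <- list()

for (i in seq_len(n_side)) {
  tr <- centriole_truth("side")  # paper-like geometry at factor 4
  mod <- model_for(seed_base + i)
  g <- generate_centriole_image(tr, mod, canvas_px = c(64L, 48L),
                                pose = list(center_px = c(32, 24),
                                            angle_deg = 0))
  f <- file.path(img_dir, sprintf("side_%02d.tif", i))
  write_image(g$image, f)
  truth_rows[[length(truth_rows) + 1L]] <- data.frame(
    id = sprintf("side_%02d", i), view = "side",
    tubulin_length_nm = tr$tubulin_length_nm,
    tubulin_diameter_nm = tr$tubulin_diameter_nm,
    marker_model = tr$marker_model,
    marker_length_nm = tr$marker_length_nm,
    marker_diameter_nm = tr$marker_diameter_nm, seed = seed_base + i)
  # longitudinal line scan along the axis, wide enough to cover the wall
  annotations[[length(annotations) + 1L]] <- data.frame(
    image = basename(f), view = "side", x0 = 14, y0 = 24, x1 = 50, y1 = 24,
    width_px = 17L)
}

for (i in seq_len(n_bottom)) {
  tr <- centriole_truth("bottom", marker_model = "proximal_ring")
  mod <- model_for(seed_base + 1000L + i)
  g <- generate_centriole_image(tr, mod, canvas_px = c(48L, 48L),
                                pose = list(center_px = c(24, 24),
                                            angle_deg = 0))
  f <- file.path(img_dir, sprintf("bottom_%02d.tif", i))
  write_image(g$image, f)
  truth_rows[[length(truth_rows) + 1L]] <- data.frame(
    id = sprintf("bottom_%02d", i), view = "bottom",
    tubulin_length_nm = NA, tubulin_diameter_nm = tr$tubulin_diameter_nm,
    marker_model = tr$marker_model, marker_length_nm = tr$marker_length_nm,
    marker_diameter_nm = tr$marker_diameter_nm, seed = seed_base + 1000L + i)
  # radial line scan through the ring centre
  annotations[[length(annotations) + 1L]] <- data.frame(
    image = basename(f), view = "bottom", x0 = 4, y0 = 24, x1 = 44, y1 = 24,
    width_px = 1L)
}

write_measurements(do.call(rbind, truth_rows), "results/ground_truth.csv")
write_measurements(do.call(rbind, annotations), "results/annotations.csv")

cat(sprintf("wrote %d side-view and %d bottom-view images to %s\n",
            n_side, n_bottom, img_dir))
cat("ground truth: results/ground_truth.csv\n")
cat("line-scan annotations: results/annotations.csv\n")
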
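#!/usr/bin/env Rscript
# Step 2: measure the simulated dataset exactly as expanded centrioles are
# measured from real gels. For each annotated image: extract the line scan,
# up-sample it 3x, detect the half-maximum extents of tubulin and marker,
# convert to biological nm with the gel expansion factor, and summarize the
# marker's position relative to the tubulin wall.
#
# Requires analysis/01_simulate_dataset.R to have been run.

suppressMessages(library(uexm))

ann <- read_measurements("results/annotations.csv")
truth <- read_measurements("results/ground_truth.csv")
cal <- calibrate_expansion(16)  # 16 mm disk from the 4 mm punch: factor 4

side_rows <- list()
diam_rows <- list()
pos_records <- list()

for (i in seq_len(nrow(ann))) {
  a <- ann[i, ]
  img <- read_image(file.path("scratch/images", a$image))
  prof <- extract_line_profile(img, c(a$x0, a$y0), c(a$x1, a$y1),
                               width_px = a$width_px)
  id <- sub("\\.tif$", "", a$image)
  if (a$view == "side") {
    m <- correct_measurement(measure_side_view(prof, id = id), cal)
    pos_records[[id]] <- relative_position(m)
    side_rows[[id]] <- data.frame(
      id = id,
      tubulin_length_nm = m$length_nm[["tubulin"]],
      marker_length_nm = m$length_nm[["marker"]],
      marker_present = !is_no_signal(m$extents$marker))
  } else {
    m <- correct_measurement(measure_bottom_view(prof, "peak_to_peak",
                                                 id = id), cal)
    mo <- correct_measurement(measure_bottom_view(prof, "outer_half_max",
                                                  id = id), cal)
    diam_rows[[id]] <- data.frame(
      id = id,
      tubulin_diameter_nm = m$diameter_nm[["tubulin"]],
      marker_diameter_nm = m$diameter_nm[["marker"]],
      tubulin_diameter_outer_nm = mo$diameter_nm[["tubulin"]])
  }
}

side <- do.call(rbind, side_rows)
diam <- do.call(rbind, diam_rows)
pos <- do.call(rbind, pos_records)
write_measurements(side, "results/lengths.csv")
write_measurements(diam, "results/diameters.csv")
write_measurements(pos, "results/relative_positions.csv")

summ <- summarize_positions(pos)
write_measurements(summ$position_stats, "results/position_summary.csv")

cat("--- side views (biological nm, expansion-corrected) ---\n")
cat(sprintf("tubulin length: %.1f +/- %.1f nm (truth %.1f)\n",
            mean(side$tubulin_length_nm), sd(side$tubulin_length_nm), 389.1))
cat(sprintf("marker length:  %.1f +/- %.1f nm (truth %.1f)\n",
            mean(side$marker_length_nm), sd(side$marker_length_nm), 107.6))
cat("--- bottom views ---\n")
cat(sprintf("tubulin diameter (peak-to-peak): %.1f +/- %.1f nm (truth %.1f)\n",
            mean(diam$tubulin_diameter_nm), sd(diam$tubulin_diameter_nm),
            241.7))
cat(sprintf("marker diameter (peak-to-peak):  %.1f +/- %.1f nm (truth %.1f)\n",
            mean(diam$marker_diameter_nm), sd(diam$marker_diameter_nm),
            240.1))
em <- cal$em_reference_nm
cat(sprintf("isotropy check: mean wall diameter within EM band %g +/- %g nm: %s\n",
            em[1], em[2],
            abs(mean(diam$tubulin_diameter_nm) - 241.7) < em[2]))
cat("--- marker position relative to tubulin start (nm) ---\n")
print(summ$position_stats)
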
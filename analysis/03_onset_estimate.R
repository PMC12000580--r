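#!/usr/bin/env Rscript
# Step 3: when is the marker first recruited to growing procentrioles?
# Simulates a growth series (93 procentrioles, as in a typical fixed-testis
# harvest; true onset 120 nm), runs each one through the full measurement
# pipeline (render profile -> measure tubulin length -> expansion-correct ->
# classify marker presence), and estimates the appearance point as the
# midpoint between the longest marker-negative and shortest marker-positive
# procentriole, with an m-out-of-n bootstrap interval.

suppressMessages(library(uexm))
dir.create("results", showWarnings = FALSE)

model <- imaging_model(pixel_size_nm = 70, psf_sigma_nm = 80,
                       photon_scale = 400, read_noise_sd = 0.05,
                       background_offset = 0.2, expansion_factor = 4)
gs <- generate_growth_series(93, c(40, 400), onset_nm = 120, model,
                             seed = 7L)
cal <- calibrate_expansion(16)

rows <- lapply(seq_len(93), function(i) {
  mod_i <- imaging_model(pixel_size_nm = 70, psf_sigma_nm = 80,
                         photon_scale = 400, read_noise_sd = 0.05,
                         background_offset = 0.2, expansion_factor = 4,
                         rng_seed = 5000L + i)
  p <- generate_profile(gs$truths[[i]], mod_i, "longitudinal")$profile
  m <- correct_measurement(measure_side_view(p, id = i), cal)
  data.frame(id = i,
             length_nm = m$length_nm[["tubulin"]],
             present = classify_presence(m, k_sigma = 3),
             true_length_nm = gs$series$length_nm[i],
             true_present = gs$series$present[i])
})
meas <- do.call(rbind, rows)
write_measurements(meas, "results/growth_series_measurements.csv")

est <- estimate_onset(meas)
ci <- bootstrap_onset_ci(meas, n_boot = 1000L, seed = 17L)
out <- data.frame(onset_nm = est$onset_nm,
                  max_absent_nm = est$max_absent_nm,
                  min_present_nm = est$min_present_nm,
                  n_absent = est$n_absent, n_present = est$n_present,
                  overlap = est$overlap_flag,
                  ci_low = ci$ci_low, ci_high = ci$ci_high)
write_measurements(out, "results/onset_estimate.csv")

cat(sprintf("procentrioles without marker: n = %d; with marker: n = %d\n",
            est$n_absent, est$n_present))
cat(sprintf("appearance point: %.1f nm (bracket %.1f - %.1f), 95%% CI [%.1f, %.1f]\n",
            est$onset_nm, est$max_absent_nm, est$min_present_nm,
            ci$ci_low, ci$ci_high))
cat(sprintf("simulated true onset: %.0f nm; presence calls matching truth: %d/93\n",
            120, sum(meas$present == meas$true_present)))
cat("note: procentrioles just above onset carry a marker below the detection\n",
    "limit, so an appearance point estimated from *classified* presence is\n",
    "biased upward toward the detectability threshold; with ground-truth\n",
    "presence the estimator is unbiased (see the methods vignette).\n", sep = "")
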
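# Independent oracles and fixture builders used across the suite. Each
# oracle re-derives the quantity by a different route than the package code
# (dense oversampling, direct enumeration with choose(), discrete
# convolution), so agreement is evidence, not tautology.

# Brute-force half-maximum crossing finder: oversample the profile 1000x by
# linear interpolation, locate the first/last dense samples at or above the
# threshold, and interpolate between the bracketing dense samples. The
# threshold definition (baseline = median of the outer 10% of samples at
# each end) is shared with the package by contract; the crossing search is
# an independent code path.
oracle_halfmax_extent <- function(positions, values, half_fraction = 0.5,
                                  oversample = 1000L) {
  n <- length(values)
  k <- max(1L, ceiling(0.1 * n))
  baseline <- median(c(values[seq_len(k)], values[seq.int(n - k + 1L, n)]))
  peak <- max(values)
  if (!(peak > baseline)) return(NULL)
  thr <- baseline + half_fraction * (peak - baseline)
  dense_x <- seq(positions[1], positions[n],
                 length.out = (n - 1L) * oversample + 1L)
  dense_v <- approx(positions, values, xout = dense_x)$y
  hit <- which(dense_v >= thr)
  interp_cross <- function(i_out, i_in) {
    # linear interpolation between the dense bracketing pair
    dense_x[i_out] + (thr - dense_v[i_out]) /
      (dense_v[i_in] - dense_v[i_out]) * (dense_x[i_in] - dense_x[i_out])
  }
  i1 <- hit[1]
  start <- if (i1 == 1L) dense_x[1] else interp_cross(i1 - 1L, i1)
  i2 <- hit[length(hit)]
  end <- if (i2 == length(dense_x)) dense_x[length(dense_x)] else
    interp_cross(i2 + 1L, i2)
  c(start = start, end = end)
}

# numerically convolve an ideal plateau [0, L] with a Gaussian on a fine
# grid and locate the half-max crossings -- oracle for blurred-edge
# localization, independent of the closed-form renderer
oracle_convolved_plateau_extent <- function(L, sigma, grid_nm = 0.5) {
  # generous flanks: filter() trims 4 sigma of NA padding from each end,
  # and the outer-10% baseline window must stay on background after that
  flank <- 4 * sigma + L / 2 + 4 * sigma + 100
  x <- seq(-flank, L + flank, by = grid_nm)
  ideal <- as.numeric(x >= 0 & x <= L)
  kx <- seq(-4 * sigma, 4 * sigma, by = grid_nm)
  kern <- dnorm(kx, sd = sigma)
  kern <- kern / sum(kern)
  sm <- stats::filter(ideal, kern, sides = 2)
  keep <- !is.na(sm)
  oracle_halfmax_extent(x[keep], as.numeric(sm[keep]), oversample = 10L)
}

# direct hypergeometric enumeration of the two-sided Fisher p-value for a
# 2x2 table, using choose() counts only (no dhyper)
oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  N <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, support) * choose(r2, c1 - support) / choose(N, c1)
  p_obs <- choose(r1, tab[1, 1]) * choose(r2, c1 - tab[1, 1]) / choose(N, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided Wilcoxon p-value by explicit enumeration of all
# m-subsets of the combined tie-free sample (combn route, independent of
# the package's dynamic program)
oracle_wilcoxon_exact <- function(x, y) {
  m <- length(x); N <- m + length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(m)])
  mu <- m * (N + 1) / 2
  combos <- combn(N, m)
  sums <- colSums(matrix(seq_len(N)[combos], nrow = m))
  mean(abs(sums - mu) >= abs(W - mu) - 1e-9)
}

# --- fixture builders -------------------------------------------------------

noiseless_model <- function(pixel_size_nm = 10, psf_sigma_nm = 0, seed = 1L,
                            expansion_factor = 4) {
  imaging_model(pixel_size_nm = pixel_size_nm, psf_sigma_nm = psf_sigma_nm,
                photon_scale = Inf, read_noise_sd = 0, background_offset = 0,
                expansion_factor = expansion_factor, rng_seed = seed)
}

# imaging model with peak SNR ~ 12 on a unit-intensity structure
snr10_model <- function(seed, pixel_size_nm = 70, psf_sigma_nm = 60) {
  imaging_model(pixel_size_nm = pixel_size_nm, psf_sigma_nm = psf_sigma_nm,
                photon_scale = 200, read_noise_sd = 0.05,
                background_offset = 0.2, expansion_factor = 4,
                rng_seed = seed)
}

# hand-built measurement with prescribed extents, for positioning tests
fake_side_measurement <- function(tub, mk = NULL, id = 1) {
  ext <- list(tubulin = structure(
    list(channel = "tubulin", start_nm = tub[1], end_nm = tub[2],
         peak_value = 1, baseline = 0, threshold_value = 0.5,
         half_fraction = 0.5, edge_clipped = FALSE),
    class = "signal_extent"))
  ext$marker <- if (is.null(mk))
    structure(list(channel = "marker", peak_value = 0, baseline = 0),
              class = "uexm_no_signal")
  else structure(
    list(channel = "marker", start_nm = mk[1], end_nm = mk[2],
         peak_value = 1, baseline = 0, threshold_value = 0.5,
         half_fraction = 0.5, edge_clipped = FALSE),
    class = "signal_extent")
  stats_df <- data.frame(channel = c("tubulin", "marker"),
                         peak = 1, peak_sustained = 1, baseline = 0,
                         noise_sd = 0)
  uexm:::new_centriole_measurement(id, "side", ext,
    lengths = c(tubulin = tub[2] - tub[1],
                marker = if (is.null(mk)) NA_real_ else mk[2] - mk[1]),
    channel_stats = stats_df, subdivision = 3L, half_fraction = 0.5)
}
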
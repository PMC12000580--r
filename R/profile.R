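#' Multi-channel projected image with physical calibration
#'
#' @param channels named list of numeric matrices (same dimensions), one per
#'   fluorescence channel.
#' @param pixel_size_nm pixel size in expanded-space nm.
#' @param expansion_factor gel expansion factor attached to the acquisition.
#' @param provenance free-text note on where the image came from.
#' @return object of class `image_plane`.
#' @export
image_plane <- function(channels, pixel_size_nm, expansion_factor,
                        provenance = "") {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(names(channels) == ""))
    stop_uexm("channels must be a named list of matrices",
              "uexm_validation_error")
  dims <- lapply(channels, dim)
  if (length(unique(lapply(dims, paste, collapse = "x"))) != 1L)
    stop_uexm("all channels must share dimensions", "uexm_validation_error")
  assert_scalar_pos(pixel_size_nm, "pixel_size_nm")
  assert_scalar_pos(expansion_factor, "expansion_factor")
  structure(list(channels = channels, pixel_size_nm = pixel_size_nm,
                 expansion_factor = expansion_factor,
                 provenance = provenance),
            class = "image_plane")
}

#' Per-channel intensity versus position along a line
#'
#' The unit of measurement for all extent detection: equally spaced positions
#' in nm with one intensity vector per channel.
#'
#' @param positions_nm strictly increasing, equally spaced positions (nm).
#' @param intensities named list of numeric vectors, one per channel, each
#'   the length of `positions_nm`.
#' @param width_px number of parallel pixel offsets averaged when the profile
#'   was extracted from an image.
#' @param space `"expanded"` or `"corrected"`.
#' @return object of class `line_profile`.
#' @export
line_profile <- function(positions_nm, intensities, width_px = 1L,
                         space = c("expanded", "corrected")) {
  space <- match.arg(space)
  n <- length(positions_nm)
  if (n < 2L) stop_uexm("a profile needs at least 2 samples",
                        "uexm_validation_error")
  d <- diff(positions_nm)
  if (any(d <= 0) || max(d) - min(d) > 1e-6 * mean(d))
    stop_uexm("positions must be strictly increasing and equally spaced",
              "uexm_validation_error")
  if (!is.list(intensities) || is.null(names(intensities)))
    stop_uexm("intensities must be a named list", "uexm_validation_error")
  if (any(vapply(intensities, length, 1L) != n))
    stop_uexm("each channel must match the number of positions",
              "uexm_validation_error")
  structure(list(positions_nm = as.numeric(positions_nm),
                 intensities = lapply(intensities, as.numeric),
                 sampling_step_nm = mean(d),
                 width_px = as.integer(width_px), space = space),
            class = "line_profile")
}

#' Extract a line profile from an image
#'
#' Samples each channel at one value per pixel step along the segment from
#' `p0` to `p1` (pixel coordinates, pixel centres at integers), averaging
#' over `width_px` parallel one-pixel-spaced offsets perpendicular to the
#' line — the usual wide line-scan used to measure centrioles. Intensities
#' are bilinearly interpolated; positions are expanded-space nm from the
#' first sample.
#'
#' @param image an [image_plane()].
#' @param p0,p1 numeric `c(x, y)` endpoints in pixel coordinates.
#' @param width_px line width in pixels (>= 1).
#' @return a [line_profile()].
#' @export
extract_line_profile <- function(image, p0, p1, width_px = 1L) {
  stopifnot(inherits(image, "image_plane"))
  if (width_px < 1L) stop_uexm("width_px must be >= 1",
                               "uexm_validation_error")
  v <- c(p1[1] - p0[1], p1[2] - p0[2])
  len <- sqrt(sum(v^2))
  if (len == 0) stop_uexm("endpoints coincide", "uexm_validation_error")
  u <- v / len
  perp <- c(-u[2], u[1])
  t <- seq(0, floor(len))
  offs <- seq_len(width_px) - (width_px + 1) / 2
  xs <- outer(t, offs, function(a, b) p0[1] + a * u[1] + b * perp[1])
  ys <- outer(t, offs, function(a, b) p0[2] + a * u[2] + b * perp[2])
  intens <- lapply(image$channels, function(ch) {
    m <- matrix(bilinear(ch, as.vector(xs), as.vector(ys)),
                nrow = length(t))
    rowMeans(m)
  })
  line_profile(t * image$pixel_size_nm, intens, width_px = width_px,
               space = "expanded")
}

#' Up-sample a profile by linear interpolation
#'
#' Artificially decreases the sampling step by an integer factor (default 3)
#' to improve the precision of sub-pixel boundary localization; intensities
#' are linearly interpolated, so the trapezoid integral is preserved and
#' `subdivision = 1` is the identity.
#'
#' @param profile a [line_profile()].
#' @param subdivision integer >= 1.
#' @return a [line_profile()] with step `sampling_step_nm / subdivision`.
#' @export
resample_profile <- function(profile, subdivision = 3L) {
  stopifnot(inherits(profile, "line_profile"))
  subdivision <- as.integer(subdivision)
  if (subdivision < 1L) stop_uexm("subdivision must be >= 1",
                                  "uexm_validation_error")
  if (subdivision == 1L) return(profile)
  x <- profile$positions_nm
  n <- length(x)
  new_x <- seq(x[1], x[n], length.out = (n - 1L) * subdivision + 1L)
  intens <- lapply(profile$intensities, function(v)
    stats::approx(x, v, xout = new_x)$y)
  line_profile(new_x, intens, width_px = profile$width_px,
               space = profile$space)
}

# robust per-channel profile statistics: baseline from the outer 10% of
# samples at each end, peak from the whole profile, the "sustained" peak
# (best level held over two consecutive samples, which a single-sample
# noise spike cannot reach) used for presence calling, and a robust noise
# estimate (MAD over a tail window of at least 4 samples per end — the
# 10% window alone is too short on small profiles to pin the noise scale).
# Noise statistics should be computed on raw samples: interpolated
# (resampled) profiles are smoother than the data and understate the noise.
profile_channel_stats <- function(profile, channel, baseline_frac = 0.1) {
  v <- profile$intensities[[channel]]
  if (is.null(v)) stop_uexm(sprintf("channel '%s' not in profile", channel),
                            "uexm_validation_error")
  n <- length(v)
  k <- max(1L, ceiling(baseline_frac * n))
  tails <- c(v[seq_len(k)], v[seq.int(n - k + 1L, n)])
  kn <- min(n %/% 2L, max(4L, k))
  noise_tails <- c(v[seq_len(kn)], v[seq.int(n - kn + 1L, n)])
  list(peak = max(v), peak_sustained = max(pmin(v[-n], v[-1L])),
       baseline = stats::median(tails),
       noise_sd = stats::mad(noise_tails),
       n_tail = length(noise_tails))
}

#' Half-maximum signal extent of one profile channel
#'
#' Locates the start and end of a fluorescent signal as the positions where
#' intensity crosses `half_fraction` (default 50%) of the peak, measured
#' above a robust baseline (median of the outer 10% of samples at each
#' profile end). Crossings are found scanning inward from each profile end —
#' so interior dips do not split the extent — and localized to sub-pixel
#' precision by linear interpolation between the bracketing samples.
#'
#' A channel whose peak does not rise above the baseline yields a "no
#' signal" result (class `uexm_no_signal`), distinguishable from an error;
#' test with [is_no_signal()].
#'
#' @param profile a [line_profile()] (>= 3 samples).
#' @param channel channel name.
#' @param half_fraction fraction of the baseline-to-peak height defining the
#'   threshold, default 0.5.
#' @return object of class `signal_extent` (fields `start_nm`, `end_nm`,
#'   `peak_value`, `baseline`, `threshold_value`, `half_fraction`,
#'   `edge_clipped`), or class `uexm_no_signal`.
#' @export
detect_extent <- function(profile, channel, half_fraction = 0.5) {
  stopifnot(inherits(profile, "line_profile"))
  x <- profile$positions_nm
  v <- profile$intensities[[channel]]
  if (is.null(v)) stop_uexm(sprintf("channel '%s' not in profile", channel),
                            "uexm_validation_error")
  if (length(v) < 3L) stop_uexm("profile needs at least 3 samples",
                                "uexm_validation_error")
  st <- profile_channel_stats(profile, channel)
  if (!(st$peak > st$baseline + 1e-12 * max(1, abs(st$peak))))
    return(structure(list(channel = channel, peak_value = st$peak,
                          baseline = st$baseline),
                     class = "uexm_no_signal"))
  thr <- st$baseline + half_fraction * (st$peak - st$baseline)

  cross_at <- function(i_lo, i_hi) {
    # linear interpolation of the threshold crossing between two samples
    x[i_lo] + (thr - v[i_lo]) / (v[i_hi] - v[i_lo]) * (x[i_hi] - x[i_lo])
  }
  n <- length(v)
  i <- which(v >= thr)[1L]
  start_clip <- i == 1L
  start_nm <- if (start_clip) x[1L] else cross_at(i - 1L, i)
  j <- n + 1L - which(rev(v) >= thr)[1L]
  end_clip <- j == n
  end_nm <- if (end_clip) x[n] else cross_at(j + 1L, j)
  structure(list(channel = channel, start_nm = start_nm, end_nm = end_nm,
                 peak_value = st$peak, baseline = st$baseline,
                 threshold_value = thr, half_fraction = half_fraction,
                 edge_clipped = start_clip || end_clip),
            class = "signal_extent")
}

#' @rdname detect_extent
#' @param x object returned by [detect_extent()].
#' @export
is_no_signal <- function(x) inherits(x, "uexm_no_signal")
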
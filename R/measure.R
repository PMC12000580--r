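#' Gel expansion calibration from a biopsy-punch disk
#'
#' The expansion factor of each gel is the diameter of the expanded gel disk
#' divided by the diameter of the punch that cut it (4 mm by convention).
#' The accompanying electron-microscopy reference band for the mature
#' centriole diameter (200 +/- 12 nm) is carried along for isotropy checks.
#'
#' @param measured_disk_mm diameter of the expanded gel disk, mm.
#' @param punch_diameter_mm punch diameter, mm (default 4).
#' @return object of class `expansion_calibration` with `factor` =
#'   `measured_disk_mm / punch_diameter_mm`.
#' @export
calibrate_expansion <- function(measured_disk_mm, punch_diameter_mm = 4) {
  assert_scalar_pos(measured_disk_mm, "measured_disk_mm")
  assert_scalar_pos(punch_diameter_mm, "punch_diameter_mm")
  structure(list(punch_diameter_mm = punch_diameter_mm,
                 measured_disk_mm = measured_disk_mm,
                 factor = measured_disk_mm / punch_diameter_mm,
                 em_reference_nm = c(200, 12)),
            class = "expansion_calibration")
}

new_centriole_measurement <- function(id, view, extents, lengths = NULL,
                                      diameters = NULL, diameter_mode = NULL,
                                      channel_stats, subdivision,
                                      half_fraction) {
  structure(list(id = id, view = view, extents = extents,
                 length_nm = lengths, diameter_nm = diameters,
                 diameter_mode = diameter_mode,
                 channel_stats = channel_stats,
                 subdivision = subdivision, half_fraction = half_fraction,
                 expansion_factor = NA_real_, space = "expanded"),
            class = "centriole_measurement")
}

#' Convert a measurement from expanded to biological space
#'
#' Divides every nm quantity of a measurement (lengths, diameters, extent
#' start/end positions) by the calibrated expansion factor. Correcting an
#' already-corrected measurement is an error, so the factor can never be
#' applied twice.
#'
#' @param m a `centriole_measurement` in expanded space.
#' @param cal an [calibrate_expansion()] result.
#' @return the measurement with all nm fields divided by `cal$factor` and
#'   `space = "corrected"`.
#' @export
correct_measurement <- function(m, cal) {
  stopifnot(inherits(m, "centriole_measurement"),
            inherits(cal, "expansion_calibration"))
  if (m$space == "corrected")
    stop_uexm("measurement is already expansion-corrected",
              "uexm_validation_error")
  f <- cal$factor
  m$length_nm <- m$length_nm / f
  m$diameter_nm <- m$diameter_nm / f
  m$extents <- lapply(m$extents, function(e) {
    if (is_no_signal(e)) return(e)
    e$start_nm <- e$start_nm / f
    e$end_nm <- e$end_nm / f
    e
  })
  m$expansion_factor <- f
  m$space <- "corrected"
  m
}

# sustained k-sigma presence gate on raw channel statistics: does this
# channel carry signal at all? (noiseless profiles fall back to any
# sustained rise above baseline)
channel_has_signal <- function(st, k_sigma = 3) {
  amp <- st$peak_sustained - st$baseline
  eps <- 1e-12 * max(1, abs(st$peak))
  if (is.na(st$noise_sd) || st$noise_sd <= eps) return(amp > eps)
  amp >= k_sigma * st$noise_sd
}

#' Measure lengths from a side-view (longitudinal) profile
#'
#' For each channel of a longitudinal line profile: up-sample by
#' `subdivision`, detect the half-maximum extent, and report the length as
#' end minus start. Channels with no detectable signal are recorded as
#' absent (not as zero length). The tubulin channel is the mandatory length
#' reference; a missing tubulin signal is an error.
#'
#' @param profile longitudinal [line_profile()] with a `tubulin` channel.
#' @param subdivision up-sampling factor passed to [resample_profile()].
#' @param half_fraction threshold fraction for [detect_extent()].
#' @param id identifier carried into the output.
#' @param k_sigma sustained-peak presence gate (noise standard deviations)
#'   below which a channel is recorded absent rather than measured.
#' @return a `centriole_measurement` (expanded space) with per-channel
#'   extents, `length_nm`, and per-channel profile statistics.
#' @export
measure_side_view <- function(profile, subdivision = 3L, half_fraction = 0.5,
                              id = NA, k_sigma = 3) {
  stopifnot(inherits(profile, "line_profile"))
  if (!"tubulin" %in% names(profile$intensities))
    stop_uexm("profile must contain a 'tubulin' channel",
              "uexm_validation_error")
  rp <- resample_profile(profile, subdivision)
  chans <- names(rp$intensities)
  extents <- lapply(chans, function(ch) {
    st <- profile_channel_stats(profile, ch)
    if (!channel_has_signal(st, k_sigma))
      return(structure(list(channel = ch, peak_value = st$peak,
                            baseline = st$baseline),
                       class = "uexm_no_signal"))
    detect_extent(rp, ch, half_fraction = half_fraction)
  })
  names(extents) <- chans
  if (is_no_signal(extents$tubulin))
    stop_uexm("no tubulin signal: cannot measure centriole length",
              "uexm_signal_error")
  lengths <- vapply(extents, function(e)
    if (is_no_signal(e)) NA_real_ else e$end_nm - e$start_nm, 1.0)
  stats_df <- do.call(rbind, lapply(chans, function(ch) {
    st <- profile_channel_stats(profile, ch)
    data.frame(channel = ch, peak = st$peak,
               peak_sustained = st$peak_sustained, baseline = st$baseline,
               noise_sd = st$noise_sd)
  }))
  new_centriole_measurement(id, "side", extents, lengths = lengths,
                            channel_stats = stats_df,
                            subdivision = subdivision,
                            half_fraction = half_fraction)
}

# 3-point quadratic (parabolic) refinement of a sampled peak position
refine_peak <- function(x, v, i) {
  if (i == 1L || i == length(v)) return(x[i])
  denom <- v[i - 1L] - 2 * v[i] + v[i + 1L]
  if (denom >= 0) return(x[i])  # not a strict local maximum
  x[i] + 0.5 * (x[i + 1L] - x[i]) * (v[i - 1L] - v[i + 1L]) / denom
}

#' Measure a ring diameter from a bottom-view (radial) profile
#'
#' The radial profile of a centriole seen from the bottom crosses the wall
#' twice, giving two peaks. Diameter conventions: `peak_to_peak` is the
#' distance between the two wall-peak positions, each refined by a 3-point
#' quadratic fit (wall-centre diameter); `outer_half_max` is the distance
#' between the outermost half-maximum crossings (outer-edge diameter, always
#' at least as large). Channels lacking two peaks above the half-max
#' threshold are recorded absent; tubulin must have both.
#'
#' @param profile radial [line_profile()] through the ring centre.
#' @param mode diameter convention, `"peak_to_peak"` (default) or
#'   `"outer_half_max"`.
#' @inheritParams measure_side_view
#' @return a `centriole_measurement` (expanded space) with `diameter_nm` per
#'   channel and the mode recorded.
#' @export
measure_bottom_view <- function(profile,
                                mode = c("peak_to_peak", "outer_half_max"),
                                subdivision = 3L, half_fraction = 0.5,
                                id = NA, k_sigma = 3) {
  mode <- match.arg(mode)
  stopifnot(inherits(profile, "line_profile"))
  if (!"tubulin" %in% names(profile$intensities))
    stop_uexm("profile must contain a 'tubulin' channel",
              "uexm_validation_error")
  rp <- resample_profile(profile, subdivision)
  x <- rp$positions_nm
  chans <- names(rp$intensities)

  one_channel <- function(ch) {
    ext <- detect_extent(rp, ch, half_fraction = half_fraction)
    if (is_no_signal(ext)) return(list(extent = ext, diameter = NA_real_))
    v <- rp$intensities[[ch]]
    # the profile must cross the ring twice: contiguous runs of samples at
    # or above the half-max threshold, separated by the lumen dip; a filled
    # or single-peaked profile has one run and is rejected
    above <- v >= ext$threshold_value
    run <- rle(above)
    run_id <- rep(seq_along(run$lengths), run$lengths)
    peak_runs <- unique(run_id[above])
    if (length(peak_runs) < 2L)
      stop_uexm(sprintf(
        "channel '%s': fewer than two peaks above half-max; not a ring", ch),
        "uexm_signal_error")
    run_peak <- function(id) {
      idx <- which(run_id == id)
      idx[which.max(v[idx])]
    }
    d <- switch(mode,
      peak_to_peak = {
        iL <- run_peak(peak_runs[1L])
        iR <- run_peak(peak_runs[length(peak_runs)])
        refine_peak(x, v, iR) - refine_peak(x, v, iL)
      },
      outer_half_max = ext$end_nm - ext$start_nm)
    list(extent = ext, diameter = d)
  }

  res <- vector("list", length(chans))
  names(res) <- chans
  for (ch in chans) {
    st <- profile_channel_stats(profile, ch)
    if (ch != "tubulin" && !channel_has_signal(st, k_sigma)) {
      res[[ch]] <- list(extent = structure(
        list(channel = ch, peak_value = st$peak, baseline = st$baseline),
        class = "uexm_no_signal"), diameter = NA_real_)
    } else {
      res[[ch]] <- one_channel(ch)
    }
  }
  extents <- lapply(res, `[[`, "extent")
  diameters <- vapply(res, `[[`, 1.0, "diameter")
  stats_df <- do.call(rbind, lapply(chans, function(ch) {
    st <- profile_channel_stats(profile, ch)
    data.frame(channel = ch, peak = st$peak,
               peak_sustained = st$peak_sustained, baseline = st$baseline,
               noise_sd = st$noise_sd)
  }))
  new_centriole_measurement(id, "bottom", extents, diameters = diameters,
                            diameter_mode = mode, channel_stats = stats_df,
                            subdivision = subdivision,
                            half_fraction = half_fraction)
}

#' Marker position relative to the tubulin reference
#'
#' Shifts a side-view measurement so the tubulin start sits at 0 and reports
#' the marker start/end in that frame; negative starts mean the marker caps
#' below the proximal wall end. Absent markers are flagged, not zeroed.
#'
#' @param m a side-view `centriole_measurement`.
#' @param marker_channel marker channel name (default `"marker"`).
#' @return one-row data frame: `id`, `tubulin_length_nm`,
#'   `marker_start_rel_nm`, `marker_end_rel_nm`, `present`, `space`.
#' @export
relative_position <- function(m, marker_channel = "marker") {
  stopifnot(inherits(m, "centriole_measurement"))
  if (m$view != "side")
    stop_uexm("relative positioning is defined for side views only",
              "uexm_validation_error")
  tub <- m$extents$tubulin
  mk <- m$extents[[marker_channel]]
  if (is.null(mk))
    stop_uexm(sprintf("channel '%s' not measured", marker_channel),
              "uexm_validation_error")
  present <- !is_no_signal(mk)
  data.frame(id = if (is.null(m$id)) NA else m$id,
             tubulin_length_nm = tub$end_nm - tub$start_nm,
             marker_start_rel_nm = if (present)
               mk$start_nm - tub$start_nm else NA_real_,
             marker_end_rel_nm = if (present)
               mk$end_nm - tub$start_nm else NA_real_,
             present = present,
             space = m$space)
}

#' Average marker position and growth curve over many centrioles
#'
#' Summarizes [relative_position()] records: mean and sample standard
#' deviation (n-1 denominator; a single record reports sd 0 with
#' `single_record = TRUE`) of the marker start and end among marker-positive
#' centrioles, plus the growth curve of start/end versus tubulin length,
#' optionally binned.
#'
#' @param records data frame of [relative_position()] rows.
#' @param bin_width_nm optional bin width for a binned growth curve.
#' @return list with `position_stats` (data frame: quantity, mean, sd, n,
#'   single_record), `growth_curve` (records sorted by tubulin length), and
#'   `binned` (bin means, or `NULL`).
#' @export
summarize_positions <- function(records, bin_width_nm = NULL) {
  pres <- records[records$present, , drop = FALSE]
  if (nrow(pres) == 0L)
    stop_uexm("no records with the marker present", "uexm_validation_error")
  single <- nrow(pres) == 1L
  sd0 <- function(v) if (length(v) < 2L) 0 else stats::sd(v)
  position_stats <- data.frame(
    quantity = c("marker_start_rel_nm", "marker_end_rel_nm"),
    mean = c(mean(pres$marker_start_rel_nm), mean(pres$marker_end_rel_nm)),
    sd = c(sd0(pres$marker_start_rel_nm), sd0(pres$marker_end_rel_nm)),
    n = nrow(pres), single_record = single)
  growth <- pres[order(pres$tubulin_length_nm), , drop = FALSE]
  binned <- NULL
  if (!is.null(bin_width_nm)) {
    assert_scalar_pos(bin_width_nm, "bin_width_nm")
    bin <- floor(growth$tubulin_length_nm / bin_width_nm)
    binned <- do.call(rbind, lapply(split(growth, bin), function(g)
      data.frame(bin_mid_nm = (bin[match(g$id[1], growth$id)] + 0.5) *
                   bin_width_nm,
                 mean_start_nm = mean(g$marker_start_rel_nm),
                 mean_end_nm = mean(g$marker_end_rel_nm),
                 n = nrow(g))))
    rownames(binned) <- NULL
  }
  list(position_stats = position_stats, growth_curve = growth,
       binned = binned)
}
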
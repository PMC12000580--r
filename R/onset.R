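#' Call marker presence on a measured centriole
#'
#' Reproducible surrogate for by-eye presence calls: the marker is scored
#' present when its profile rises at least `k_sigma` noise standard
#' deviations above the baseline (both estimated from the profile tails and
#' stored in the measurement) *sustained over two consecutive samples* — a
#' real blurred marker spans many samples, while a single-sample noise spike
#' does not, so the sustained-peak rule keeps the false-positive rate of the
#' k-sigma threshold low across a whole profile. On noiseless profiles
#' (noise sd ~ 0) any sustained peak strictly above baseline counts.
#'
#' @param m a `centriole_measurement` from [measure_side_view()].
#' @param marker_channel marker channel name.
#' @param k_sigma detection threshold in noise standard deviations.
#' @return logical.
#' @export
classify_presence <- function(m, marker_channel = "marker", k_sigma = 3) {
  stopifnot(inherits(m, "centriole_measurement"))
  st <- m$channel_stats[m$channel_stats$channel == marker_channel, ]
  if (nrow(st) == 0L)
    stop_uexm(sprintf("channel '%s' not measured", marker_channel),
              "uexm_validation_error")
  amp <- st$peak_sustained - st$baseline
  eps <- 1e-12 * max(1, abs(st$peak))
  if (is.na(st$noise_sd) || st$noise_sd <= eps) return(amp > eps)
  amp >= k_sigma * st$noise_sd
}

#' Appearance point of a marker over a growth series
#'
#' Estimates the procentriole length at which a marker is first recruited as
#' the midpoint between the longest procentriole lacking the marker and the
#' shortest procentriole bearing it. When the two groups interleave the same
#' midpoint rule is still applied and `overlap_flag` is set rather than
#' silently switching estimator.
#'
#' @param records data frame with columns `length_nm` and logical `present`.
#' @return object of class `onset_estimate`: `onset_nm`, bracketing lengths
#'   `max_absent_nm` / `min_present_nm`, group sizes, `overlap_flag`.
#' @export
estimate_onset <- function(records) {
  if (!all(c("length_nm", "present") %in% names(records)))
    stop_uexm("records need columns 'length_nm' and 'present'",
              "uexm_validation_error")
  ab <- records$length_nm[!records$present]
  pr <- records$length_nm[records$present]
  if (length(ab) == 0L || length(pr) == 0L)
    stop_uexm("need at least one marker-absent and one marker-present record",
              "uexm_validation_error")
  max_absent <- max(ab)
  min_present <- min(pr)
  structure(list(onset_nm = (max_absent + min_present) / 2,
                 max_absent_nm = max_absent, min_present_nm = min_present,
                 n_absent = length(ab), n_present = length(pr),
                 overlap_flag = max_absent > min_present,
                 ci_low = NA_real_, ci_high = NA_real_),
            class = "onset_estimate")
}

#' Percentile bootstrap interval for the appearance point
#'
#' Resamples the presence/length records with replacement and recomputes the
#' midpoint onset on each resample, reporting the percentile interval of the
#' resampled onsets; resamples in which one group vanishes are redrawn (their
#' number is reported). Because the midpoint estimator is built from two
#' extreme order statistics, the classical n-out-of-n bootstrap is
#' inconsistent for it and undercovers; resamples are therefore of size
#' `m = subsample_fraction * n` (m-out-of-n bootstrap, default m = n/2), the
#' standard remedy for non-regular estimators, which gives a conservative
#' interval.
#'
#' @inheritParams estimate_onset
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @param subsample_fraction resample size as a fraction of `n` (default
#'   0.5); resamples are drawn with replacement and never smaller than 4.
#' @return list: `ci_low`, `ci_high`, `n_boot`, `n_redrawn`, `level`.
#' @export
bootstrap_onset_ci <- function(records, n_boot = 1000L, seed = 1L,
                               level = 0.95, subsample_fraction = 0.5) {
  est <- estimate_onset(records)  # validates preconditions
  if (est$n_absent < 2L || est$n_present < 2L)
    warning("fewer than 2 records in a group: bootstrap CI is degenerate")
  if (subsample_fraction <= 0 || subsample_fraction > 1)
    stop_uexm("subsample_fraction must lie in (0, 1]", "uexm_validation_error")
  len <- records$length_nm
  pres <- records$present
  n <- length(len)
  m <- min(n, max(4L, floor(subsample_fraction * n)))
  withr::with_seed(seed, {
    onsets <- numeric(n_boot)
    n_redrawn <- 0L
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, m, replace = TRUE)
        if (any(pres[idx]) && any(!pres[idx])) break
        n_redrawn <- n_redrawn + 1L
      }
      onsets[b] <- (max(len[idx][!pres[idx]]) + min(len[idx][pres[idx]])) / 2
    }
    alpha <- (1 - level) / 2
    ci <- unname(stats::quantile(onsets, c(alpha, 1 - alpha), type = 7))
    list(ci_low = ci[1], ci_high = ci[2], n_boot = n_boot,
         n_redrawn = n_redrawn, level = level)
  })
}
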
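#' Ground truth of one synthetic expanded centriole
#'
#' Describes the geometry of a simulated centriole in expanded (gel-space)
#' nanometres: the microtubule wall is a hollow cylinder seen either from the
#' side (two parallel wall lines after projection) or from the bottom (a
#' ring), and an optional proximal marker is drawn as a cap (filled disc
#' spanning the lumen), a ring, or a sleeve around the wall. Biological
#' dimensions are recovered only by dividing measurements by the gel
#' expansion factor, mirroring how expansion-microscopy data are analysed.
#'
#' Defaults correspond to a mature human centriole carrying a proximal
#' ALMS1-like cap, at a gel expansion factor of 4: tubulin length
#' 389.1 nm, tubulin diameter 241.7 nm, marker length 107.6 nm, marker
#' diameter 240.1 nm (biological values, stored here multiplied by 4).
#'
#' @param view `"side"` (projected lateral view) or `"bottom"` (ring view).
#' @param tubulin_length_nm wall length in expanded nm (side view only).
#' @param tubulin_diameter_nm wall-centre diameter, expanded nm.
#' @param wall_thickness_nm thickness of the drawn wall, expanded nm.
#' @param marker_model `"cap"`, `"proximal_ring"`, `"sleeve"` or `"absent"`.
#' @param marker_length_nm longitudinal extent of the marker, expanded nm;
#'   forced to 0 when `marker_model = "absent"`.
#' @param marker_diameter_nm marker ring/cap diameter, expanded nm.
#' @param marker_offset_nm start of the marker relative to the proximal
#'   tubulin end (negative values cap below the wall), expanded nm.
#' @param intensity_scale named numeric vector of per-channel brightness
#'   multipliers; names `"tubulin"` and `"marker"`.
#' @return an object of class `centriole_truth`.
#' @export
centriole_truth <- function(view = c("side", "bottom"),
                            tubulin_length_nm = 389.1 * 4,
                            tubulin_diameter_nm = 241.7 * 4,
                            wall_thickness_nm = 25 * 4,
                            marker_model = c("cap", "proximal_ring",
                                             "sleeve", "absent"),
                            marker_length_nm = 107.6 * 4,
                            marker_diameter_nm = 240.1 * 4,
                            marker_offset_nm = -20 * 4,
                            intensity_scale = c(tubulin = 1, marker = 1)) {
  view <- match.arg(view)
  marker_model <- match.arg(marker_model)
  if (marker_model == "absent") marker_length_nm <- 0
  if (view == "side") assert_scalar_pos(tubulin_length_nm, "tubulin_length_nm")
  assert_scalar_pos(tubulin_diameter_nm, "tubulin_diameter_nm")
  assert_scalar_pos(wall_thickness_nm, "wall_thickness_nm")
  if (marker_model != "absent") {
    assert_scalar_pos(marker_length_nm, "marker_length_nm")
    assert_scalar_pos(marker_diameter_nm, "marker_diameter_nm")
  } else if (marker_length_nm != 0) {
    stop_uexm("marker_length_nm must be 0 when marker_model is 'absent'",
              "uexm_validation_error")
  }
  if (!all(c("tubulin", "marker") %in% names(intensity_scale)) ||
      any(intensity_scale <= 0))
    stop_uexm("intensity_scale needs positive 'tubulin' and 'marker' entries",
              "uexm_validation_error")
  structure(list(view = view,
                 tubulin_length_nm = tubulin_length_nm,
                 tubulin_diameter_nm = tubulin_diameter_nm,
                 wall_thickness_nm = wall_thickness_nm,
                 marker_model = marker_model,
                 marker_length_nm = marker_length_nm,
                 marker_diameter_nm = marker_diameter_nm,
                 marker_offset_nm = marker_offset_nm,
                 intensity_scale = intensity_scale),
            class = "centriole_truth")
}

#' Imaging model for the synthetic generator
#'
#' Bundles the acquisition parameters used when rendering synthetic expanded
#' centrioles: sampling, optical blur, noise, and the gel expansion factor.
#' All spatial parameters are in expanded (gel) space. The noise model is
#' `Poisson(photon_scale * ideal) / photon_scale + Normal(0, read_noise_sd)
#' + background_offset`, so the expected image equals the noiseless ideal
#' plus the offset, and `photon_scale = Inf` is the exact noiseless limit.
#' Peak signal-to-noise on a unit-intensity structure is roughly
#' `sqrt(photon_scale)`.
#'
#' @param pixel_size_nm pixel size in expanded-space nm.
#' @param psf_sigma_nm Gaussian point-spread-function sigma, expanded nm.
#' @param background_offset constant background added after noise.
#' @param photon_scale Poisson rate multiplier; `Inf` disables shot noise.
#' @param read_noise_sd Gaussian read noise standard deviation.
#' @param expansion_factor gel expansion factor (post/pre expansion size).
#' @param rng_seed integer seed; identical seed and parameters give
#'   bit-identical output.
#' @return an object of class `imaging_model`.
#' @export
imaging_model <- function(pixel_size_nm = 70, psf_sigma_nm = 100,
                          background_offset = 0, photon_scale = 200,
                          read_noise_sd = 0, expansion_factor = 4,
                          rng_seed = 1L) {
  assert_scalar_pos(pixel_size_nm, "pixel_size_nm")
  assert_scalar_nonneg(psf_sigma_nm, "psf_sigma_nm")
  assert_scalar_nonneg(background_offset, "background_offset")
  if (!(is.numeric(photon_scale) && length(photon_scale) == 1L &&
        (is.infinite(photon_scale) || photon_scale > 0)))
    stop_uexm("photon_scale must be positive (Inf = noiseless)",
              "uexm_validation_error")
  assert_scalar_nonneg(read_noise_sd, "read_noise_sd")
  assert_scalar_pos(expansion_factor, "expansion_factor")
  structure(list(pixel_size_nm = pixel_size_nm,
                 psf_sigma_nm = psf_sigma_nm,
                 background_offset = background_offset,
                 photon_scale = photon_scale,
                 read_noise_sd = read_noise_sd,
                 expansion_factor = expansion_factor,
                 rng_seed = as.integer(rng_seed)),
            class = "imaging_model")
}
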
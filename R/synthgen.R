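# Synthetic expanded-centriole generator.
#
# Ideal (noiseless) structures are defined in continuous expanded-space
# coordinates and area-sampled onto the pixel grid before any PSF blur, so
# that pixel-quantization does not bias the length/diameter tests. For 1D
# profiles the boxcar-convolved-with-Gaussian pixel average has a closed
# form, used directly.

# pixel-averaged value of indicator([a,b]) convolved with Gaussian(sigma),
# for pixels with the given edges (length n+1 -> n values)
box_segment_profile <- function(edges, a, b, sigma) {
  n <- length(edges) - 1L
  if (b <= a) return(numeric(n))
  lo <- edges[-(n + 1L)]
  hi <- edges[-1L]
  if (sigma <= 0) {
    return(pmax(0, pmin(hi, b) - pmax(lo, a)) / (hi - lo))
  }
  # antiderivative of pnorm((x - m)/sigma) is sigma * G((x - m)/sigma),
  # G(z) = z*pnorm(z) + dnorm(z)
  G <- function(z) z * stats::pnorm(z) + stats::dnorm(z)
  Fa <- function(x) sigma * G((x - a) / sigma)
  Fb <- function(x) sigma * G((x - b) / sigma)
  ((Fa(hi) - Fa(lo)) - (Fb(hi) - Fb(lo))) / (hi - lo)
}

# Poisson shot noise + Gaussian read noise + constant offset; the noiseless
# (photon_scale = Inf) limit is exactly the ideal signal
apply_noise <- function(ideal, model) {
  x <- pmax(ideal, 0)
  if (is.finite(model$photon_scale))
    x <- stats::rpois(length(x), model$photon_scale * x) / model$photon_scale
  if (model$read_noise_sd > 0)
    x <- x + stats::rnorm(length(x), 0, model$read_noise_sd)
  x + model$background_offset
}

# marker longitudinal segment [start, end] relative to proximal tubulin end
marker_segment <- function(truth) {
  c(truth$marker_offset_nm, truth$marker_offset_nm + truth$marker_length_nm)
}

#' Generate a synthetic line profile across an expanded centriole
#'
#' Renders the ideal per-channel intensity profile of one centriole along its
#' long axis (side view) or across the ring (bottom view), convolves it with
#' the Gaussian PSF, area-samples it on the pixel grid, and applies the
#' imaging noise model. Positions are in expanded-space nm, with the origin
#' at the proximal tubulin end (longitudinal) or the ring centre (radial).
#'
#' @param truth a [centriole_truth()].
#' @param model an [imaging_model()].
#' @param axis `"longitudinal"` (requires side view) or `"radial"` (requires
#'   bottom view).
#' @return a list with elements `profile` (a [line_profile()] with channels
#'   `tubulin` and `marker`) and `truth` (the input, echoed for harnesses).
#' @export
generate_profile <- function(truth, model,
                             axis = c("longitudinal", "radial")) {
  axis <- match.arg(axis)
  stopifnot(inherits(truth, "centriole_truth"),
            inherits(model, "imaging_model"))
  if (axis == "longitudinal" && truth$view != "side")
    stop_uexm("longitudinal profiles require a side-view truth",
              "uexm_validation_error")
  if (axis == "radial" && truth$view != "bottom")
    stop_uexm("radial profiles require a bottom-view truth",
              "uexm_validation_error")
  px <- model$pixel_size_nm
  sigma <- model$psf_sigma_nm
  # flanking background: at least 3 sigma of blur plus a quarter of the
  # structure span, so the outer-10% baseline window never touches signal
  span <- if (axis == "longitudinal") truth$tubulin_length_nm else
    max(truth$tubulin_diameter_nm, truth$marker_diameter_nm) +
      truth$wall_thickness_nm
  margin <- px * ceiling((3 * sigma + 2 * px + 0.25 * span) / px)

  if (axis == "longitudinal") {
    L <- truth$tubulin_length_nm
    edges <- seq(-margin, px * ceiling((L + margin) / px), by = px)
    tub <- box_segment_profile(edges, 0, L, sigma)
    mk <- numeric(length(tub))
    if (truth$marker_model != "absent") {
      seg <- marker_segment(truth)
      mk <- box_segment_profile(edges, seg[1], seg[2], sigma)
    }
  } else {
    t2 <- truth$wall_thickness_nm / 2
    R <- px * ceiling((span / 2 + margin) / px)
    edges <- seq(-R, R, by = px)
    r_t <- truth$tubulin_diameter_nm / 2
    tub <- box_segment_profile(edges, -r_t - t2, -r_t + t2, sigma) +
      box_segment_profile(edges, r_t - t2, r_t + t2, sigma)
    mk <- numeric(length(tub))
    if (truth$marker_model == "cap") {
      r_m <- truth$marker_diameter_nm / 2
      mk <- box_segment_profile(edges, -r_m, r_m, sigma)
    } else if (truth$marker_model %in% c("proximal_ring", "sleeve")) {
      r_m <- truth$marker_diameter_nm / 2
      mk <- box_segment_profile(edges, -r_m - t2, -r_m + t2, sigma) +
        box_segment_profile(edges, r_m - t2, r_m + t2, sigma)
    }
  }

  tub <- tub * truth$intensity_scale[["tubulin"]]
  mk <- mk * truth$intensity_scale[["marker"]]
  noisy <- withr::with_seed(model$rng_seed, {
    list(tubulin = apply_noise(tub, model), marker = apply_noise(mk, model))
  })
  positions <- (edges[-length(edges)] + edges[-1L]) / 2
  prof <- line_profile(positions, noisy, width_px = 1L, space = "expanded")
  list(profile = prof, truth = truth)
}

#' Render a synthetic expanded-centriole image
#'
#' Draws one centriole on a pixel canvas at a given position and in-plane
#' angle: channel `tubulin` holds the wall (two parallel bars in side view, a
#' ring in bottom view), channel `marker` the proximal marker per its model.
#' Structures are evaluated in continuous coordinates on a 3x3 subpixel grid
#' and mean-pooled (area sampling) before PSF convolution and noise.
#'
#' @param truth a [centriole_truth()].
#' @param model an [imaging_model()].
#' @param canvas_px integer pair `c(nx, ny)`.
#' @param pose list with `center_px` (pixel coordinates `c(x, y)` of the
#'   structure centre) and `angle_deg` (in-plane rotation of the long axis).
#' @return list with `image` (an [image_plane()]) and `truth` (input truth
#'   with the pose recorded as attribute `"pose"`).
#' @export
generate_centriole_image <- function(truth, model,
                                     canvas_px = c(64L, 64L),
                                     pose = list(center_px = canvas_px / 2,
                                                 angle_deg = 0)) {
  stopifnot(inherits(truth, "centriole_truth"),
            inherits(model, "imaging_model"))
  nx <- as.integer(canvas_px[1]); ny <- as.integer(canvas_px[2])
  px <- model$pixel_size_nm
  cx <- pose$center_px[1]; cy <- pose$center_px[2]
  ang <- (pose$angle_deg %||% 0) * pi / 180

  half_len <- if (truth$view == "side") truth$tubulin_length_nm / 2 else 0
  mk_seg <- marker_segment(truth) - half_len   # centre-origin coordinates
  r_out <- max(truth$tubulin_diameter_nm, truth$marker_diameter_nm) / 2 +
    truth$wall_thickness_nm / 2
  bound <- sqrt(max(half_len, abs(mk_seg))^2 + r_out^2) +
    3 * model$psf_sigma_nm
  if (cx - bound / px < 0.5 || cx + bound / px > nx + 0.5 ||
      cy - bound / px < 0.5 || cy + bound / px > ny + 0.5)
    stop_uexm("structure (plus 3 sigma of PSF) exceeds the canvas",
              "uexm_validation_error")

  ss <- 3L
  off <- (seq_len(ss) - (ss + 1) / 2) / ss
  gx <- rep(seq_len(nx), each = ss) + rep(off, nx)
  gy <- rep(seq_len(ny), each = ss) + rep(off, ny)
  X <- matrix(rep(gx, each = length(gy)), length(gy), length(gx))
  Y <- matrix(rep(gy, times = length(gx)), length(gy), length(gx))
  # structure frame: rotate pixel offsets back by -angle, convert to nm
  dx <- (X - cx) * px; dy <- (Y - cy) * px
  xs <- cos(ang) * dx + sin(ang) * dy
  ys <- -sin(ang) * dx + cos(ang) * dy

  t2 <- truth$wall_thickness_nm / 2
  if (truth$view == "side") {
    along <- xs >= -half_len & xs <= half_len
    tub <- along & abs(abs(ys) - truth$tubulin_diameter_nm / 2) <= t2
    m_along <- xs >= mk_seg[1] & xs <= mk_seg[2]
    mk <- switch(truth$marker_model,
      absent = matrix(FALSE, nrow(xs), ncol(xs)),
      cap = m_along & abs(ys) <= truth$marker_diameter_nm / 2,
      m_along & abs(abs(ys) - truth$marker_diameter_nm / 2) <= t2)
  } else {
    r <- sqrt(xs^2 + ys^2)
    tub <- abs(r - truth$tubulin_diameter_nm / 2) <= t2
    mk <- switch(truth$marker_model,
      absent = matrix(FALSE, nrow(r), ncol(r)),
      cap = r <= truth$marker_diameter_nm / 2,
      abs(r - truth$marker_diameter_nm / 2) <= t2)
  }

  render <- function(ind, scale) {
    ideal <- pool_mean(ind + 0, ss) * scale
    gaussian_blur(ideal, model$psf_sigma_nm / px)
  }
  tub_i <- render(tub, truth$intensity_scale[["tubulin"]])
  mk_i <- render(mk, truth$intensity_scale[["marker"]])
  channels <- withr::with_seed(model$rng_seed, {
    list(tubulin = matrix(apply_noise(tub_i, model), ny, nx),
         marker = matrix(apply_noise(mk_i, model), ny, nx))
  })
  img <- image_plane(channels, pixel_size_nm = px,
                     expansion_factor = model$expansion_factor,
                     provenance = sprintf("uexm synthetic, seed %d",
                                          model$rng_seed))
  attr(truth, "pose") <- pose
  list(image = img, truth = truth)
}

#' Generate a procentriole growth series with known marker onset
#'
#' Draws `n` procentriole lengths uniformly over a biological length range;
#' the proximal marker is present on a procentriole if and only if its length
#' reaches `onset_nm`. Above onset the marker extent grows linearly,
#' `min(marker_length_max_nm, 0.5 * (length - onset))`, a simple monotone
#' recruitment rule. Truth geometries are stored in expanded space (biological
#' values times the model's expansion factor).
#'
#' @param n number of procentrioles (>= 2).
#' @param length_range_nm biological length range, nm, e.g. `c(40, 400)`.
#' @param onset_nm biological length at which the marker first appears.
#' @param model an [imaging_model()]; supplies the expansion factor and is
#'   stored for downstream rendering.
#' @param seed integer seed for the length draw.
#' @param marker_length_max_nm saturating marker extent, biological nm.
#' @return an object of class `growth_series`: list with `series` (data frame
#'   `id`, `length_nm`, `present`, `marker_length_nm`; biological nm) and
#'   `truths` (list of [centriole_truth()] in expanded space).
#' @export
generate_growth_series <- function(n, length_range_nm, onset_nm, model,
                                   seed, marker_length_max_nm = 107.6) {
  if (n < 2) stop_uexm("n must be at least 2", "uexm_validation_error")
  if (length_range_nm[1] <= 0 || diff(length_range_nm) <= 0)
    stop_uexm("length_range_nm must be a positive increasing pair",
              "uexm_validation_error")
  if (onset_nm < length_range_nm[1] || onset_nm > length_range_nm[2])
    warning("onset_nm lies outside length_range_nm; ",
            "all procentrioles will fall on one side of onset")
  f <- model$expansion_factor
  len <- withr::with_seed(seed,
    stats::runif(n, length_range_nm[1], length_range_nm[2]))
  present <- len >= onset_nm
  mk_len <- ifelse(present,
                   pmin(marker_length_max_nm, 0.5 * (len - onset_nm)), 0)
  truths <- lapply(seq_len(n), function(i) {
    centriole_truth(view = "side",
                    tubulin_length_nm = len[i] * f,
                    marker_model = if (present[i] && mk_len[i] > 0)
                      "cap" else "absent",
                    marker_length_nm = if (present[i] && mk_len[i] > 0)
                      mk_len[i] * f else 0,
                    marker_offset_nm = 0)
  })
  structure(list(series = data.frame(id = seq_len(n), length_nm = len,
                                     present = present,
                                     marker_length_nm = mk_len),
                 truths = truths, onset_nm = onset_nm, model = model,
                 seed = seed),
            class = "growth_series")
}

#' Sample a spermatocyte centriole-count table from the lineage model
#'
#' Draws `n_cells` final-generation germ cells from the duplication-failure
#' mixture distribution of [predict_distribution()]: a fraction `mixture_f`
#' of cells descend from lineages whose duplication failed at the 4-cell
#' stage (half of those end with no centriole), the rest from 8-cell-stage
#' failures (all end with a single centriole).
#'
#' @param n_cells number of cells to sample.
#' @param mixture_f fraction in `[0, 1]` of cells from 4-cell-stage failures.
#' @param seed integer seed.
#' @return named integer vector of counts over centriole-count classes
#'   (`"0C"`, `"1C"`, ...).
#' @export
generate_cyst_counts <- function(n_cells, mixture_f, seed) {
  if (mixture_f < 0 || mixture_f > 1)
    stop_uexm("mixture_f must lie in [0, 1]", "uexm_validation_error")
  p <- predict_distribution(mixture_f)
  draws <- withr::with_seed(seed,
    sample(names(p), n_cells, replace = TRUE, prob = p))
  counts <- table(factor(draws, levels = names(p)))
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}
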
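# Fluorescence quantification at centrioles: thresholded or square ROIs,
# background subtraction, and internal-control normalization.

#' Segment a thresholded ROI around a seed point
#'
#' Thresholds the channel (Otsu computed on a local window centred on the
#' seed — centriole spots are sparse in large fields — or a fixed value) and
#' returns the connected component of above-threshold pixels containing the
#' seed.
#'
#' @param image an [image_plane()].
#' @param channel channel name to segment.
#' @param seed_point pixel coordinates `c(x, y)` inside the spot.
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_value threshold when `method = "fixed"`.
#' @param window_px side of the local Otsu window (default 64).
#' @return logical mask matrix; the threshold used is attached as attribute
#'   `"threshold"`.
#' @export
segment_roi <- function(image, channel, seed_point,
                        method = c("otsu", "fixed"), fixed_value = NULL,
                        window_px = 64L) {
  method <- match.arg(method)
  stopifnot(inherits(image, "image_plane"))
  ch <- image$channels[[channel]]
  if (is.null(ch)) stop_uexm(sprintf("channel '%s' not in image", channel),
                             "uexm_validation_error")
  sx <- round(seed_point[1]); sy <- round(seed_point[2])
  if (sx < 1 || sx > ncol(ch) || sy < 1 || sy > nrow(ch))
    stop_uexm("seed point outside the image", "uexm_validation_error")

  if (method == "otsu") {
    h <- window_px %/% 2L
    xr <- max(1L, sx - h):min(ncol(ch), sx + h)
    yr <- max(1L, sy - h):min(nrow(ch), sy + h)
    w <- ch[yr, xr]
    rng <- range(w)
    if (diff(rng) <= 0)
      stop_uexm("flat window: cannot compute an Otsu threshold",
                "uexm_signal_error")
    thr <- EBImage::otsu((w - rng[1]) / diff(rng), range = c(0, 1),
                         levels = 256L) * diff(rng) + rng[1]
  } else {
    if (is.null(fixed_value))
      stop_uexm("fixed_value required for method = 'fixed'",
                "uexm_validation_error")
    thr <- fixed_value
  }
  bin <- ch >= thr
  if (!any(bin)) stop_uexm("empty ROI: no pixel above the threshold",
                           "uexm_signal_error")
  lab <- EBImage::bwlabel(bin)
  seed_lab <- lab[sy, sx]
  if (seed_lab == 0)
    stop_uexm("empty ROI: seed point below the threshold",
              "uexm_signal_error")
  mask <- lab == seed_lab
  attr(mask, "threshold") <- thr
  mask
}

#' Axis-aligned square ROI mask
#'
#' @param center pixel coordinates `c(x, y)`.
#' @param half_width_px half side; the mask has side `2 * half_width_px + 1`.
#' @param dim_px image dimensions `c(nx, ny)` the mask must fit inside.
#' @return logical mask matrix of dimensions `c(ny, nx)`.
#' @export
square_roi <- function(center, half_width_px, dim_px) {
  cx <- round(center[1]); cy <- round(center[2])
  nx <- dim_px[1]; ny <- dim_px[2]
  if (cx - half_width_px < 1 || cx + half_width_px > nx ||
      cy - half_width_px < 1 || cy + half_width_px > ny)
    stop_uexm("square ROI exits the image", "uexm_validation_error")
  mask <- matrix(FALSE, ny, nx)
  mask[(cy - half_width_px):(cy + half_width_px),
       (cx - half_width_px):(cx + half_width_px)] <- TRUE
  mask
}

annulus_background <- function(ch, mask, inner_px = 2L, outer_px = 5L) {
  outer <- EBImage::dilate(mask + 0, EBImage::makeBrush(2L * outer_px + 1L,
                                                        "disc")) > 0
  inner <- EBImage::dilate(mask + 0, EBImage::makeBrush(2L * inner_px + 1L,
                                                        "disc")) > 0
  ann <- outer & !inner
  if (!any(ann))
    stop_uexm("empty background annulus", "uexm_signal_error")
  stats::median(ch[ann])
}

#' Integrated, background-subtracted ROI intensity
#'
#' Sums the channel over the mask, subtracts a per-pixel background estimate
#' (median of an annulus around the mask, or a global low percentile of the
#' channel), and — when an internal-control channel is given — divides by the
#' control's net intensity quantified on the *same* mask with the same
#' background method.
#'
#' @param image an [image_plane()].
#' @param channel target channel name.
#' @param mask logical ROI mask.
#' @param background `"annulus"` (default) or `"global_percentile"`.
#' @param control_channel optional internal-control channel name.
#' @param percentile percentile for the global background (default 0.1).
#' @param annulus_inner_px,annulus_outer_px annulus dilation radii.
#' @return one-row data frame of class fields: `roi_kind` (`NA`, set by
#'   callers), `area_px`, `integrated_intensity`, `background_per_px`,
#'   `net_intensity`, `control_net_intensity`, `normalized`.
#' @export
quantify_roi <- function(image, channel, mask,
                         background = c("annulus", "global_percentile"),
                         control_channel = NULL, percentile = 0.1,
                         annulus_inner_px = 2L, annulus_outer_px = 5L) {
  background <- match.arg(background)
  stopifnot(inherits(image, "image_plane"))
  ch <- image$channels[[channel]]
  if (is.null(ch)) stop_uexm(sprintf("channel '%s' not in image", channel),
                             "uexm_validation_error")
  if (!any(mask)) stop_uexm("empty mask", "uexm_validation_error")
  net_of <- function(chan) {
    bg <- switch(background,
      annulus = annulus_background(chan, mask, annulus_inner_px,
                                   annulus_outer_px),
      global_percentile = unname(stats::quantile(chan, percentile, type = 7)))
    integrated <- sum(chan[mask])
    list(integrated = integrated, bg = bg,
         net = integrated - bg * sum(mask))
  }
  tgt <- net_of(ch)
  ctrl_net <- NA_real_
  normalized <- NA_real_
  if (!is.null(control_channel)) {
    cc <- image$channels[[control_channel]]
    if (is.null(cc))
      stop_uexm(sprintf("control channel '%s' not in image", control_channel),
                "uexm_validation_error")
    ctrl_net <- net_of(cc)$net
    normalized <- tgt$net / ctrl_net
  }
  data.frame(area_px = sum(mask), integrated_intensity = tgt$integrated,
             background_per_px = tgt$bg, net_intensity = tgt$net,
             control_net_intensity = ctrl_net, normalized = normalized)
}

#' Batch ROI quantification with optional blinding
#'
#' Quantifies one ROI per annotation row across a set of images, producing a
#' tidy per-centriole table keyed by stage (and genotype). With
#' `anonymize = TRUE` the genotype column is withheld from the measurement
#' table and replaced by a shuffled anonymous id; the sealed id-to-genotype
#' key is returned separately (and can be written to its own file),
#' mirroring blind scoring by a third party.
#'
#' @param annotations data frame with columns `image` (name into `images`),
#'   `x`, `y`, `stage`, `genotype`, `roi_kind` (`"threshold"` or `"square"`),
#'   and `half_width_px` for square ROIs.
#' @param images named list of [image_plane()] objects.
#' @param channel target channel.
#' @param control_channel optional internal-control channel.
#' @param background background method, see [quantify_roi()].
#' @param n_per_stage expected annotations per stage (default 10); fewer
#'   triggers a warning, not an error.
#' @param anonymize withhold genotype behind a shuffled key?
#' @param key_seed seed for the anonymization shuffle.
#' @return list with `table` (one row per ROI) and `key` (`NULL` unless
#'   anonymized: data frame anon_id -> genotype).
#' @export
batch_quantify <- function(annotations, images, channel,
                           control_channel = NULL,
                           background = c("annulus", "global_percentile"),
                           n_per_stage = 10L, anonymize = FALSE,
                           key_seed = 1L) {
  background <- match.arg(background)
  need <- c("image", "x", "y", "stage", "genotype", "roi_kind")
  if (!all(need %in% names(annotations)))
    stop_uexm(paste("annotations need columns:", paste(need, collapse = ", ")),
              "uexm_validation_error")
  missing_img <- setdiff(unique(annotations$image), names(images))
  if (length(missing_img) > 0L)
    stop_uexm(paste("missing images:", paste(missing_img, collapse = ", ")),
              "uexm_io_error")
  tallies <- table(annotations$stage)
  if (any(tallies < n_per_stage))
    warning(sprintf("fewer than %d annotations for stage(s): %s",
                    n_per_stage,
                    paste(names(tallies)[tallies < n_per_stage],
                          collapse = ", ")))
  rows <- lapply(seq_len(nrow(annotations)), function(i) {
    an <- annotations[i, ]
    img <- images[[an$image]]
    mask <- switch(as.character(an$roi_kind),
      threshold = segment_roi(img, channel, c(an$x, an$y)),
      square = square_roi(c(an$x, an$y), an$half_width_px,
                          c(ncol(img$channels[[1]]),
                            nrow(img$channels[[1]]))),
      stop_uexm(sprintf("unknown roi_kind '%s'", an$roi_kind),
                "uexm_validation_error"))
    q <- quantify_roi(img, channel, mask, background = background,
                      control_channel = control_channel)
    cbind(data.frame(image = an$image, centriole_id = i, stage = an$stage,
                     genotype = an$genotype,
                     roi_kind = as.character(an$roi_kind)), q)
  })
  out <- do.call(rbind, rows)
  key <- NULL
  if (anonymize) {
    anon <- withr::with_seed(key_seed, sample(nrow(out)))
    key <- data.frame(anon_id = anon, genotype = out$genotype,
                      image = out$image, centriole_id = out$centriole_id)
    out$genotype <- NULL
    out$anon_id <- anon
  }
  list(table = out, key = key)
}
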
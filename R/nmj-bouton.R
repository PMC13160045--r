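#' Normalized sum of channels
#'
#' Divides each channel by its mean and sums; the output mean equals the
#' number of channels exactly. This is the composite used to build the 3D
#' presynaptic mask from the Nwk/Dynamin/Brp channels.
#'
#' @param channels List of numeric arrays of identical shape, each with a
#'   strictly positive mean.
#' @return Array of the same shape.
#' @export
normalized_sum <- function(channels) {
  stopifnot(is.list(channels), length(channels) >= 1L)
  out <- NULL
  for (ch in channels) {
    m <- mean(ch)
    if (!is.finite(m) || m <= 0) stop("channel with zero mean")
    out <- if (is.null(out)) ch / m else out + ch / m
  }
  out
}

#' 3D presynaptic bouton mask
#'
#' Pipeline: normalized sum of the mask-recipe channels
#' (`cfg$nmj_mask_roles`, by default Nwk + Dynamin + Brp), per-slice
#' gaussian blur (`cfg$nmj_gaussian_sigma_px`), automatic intensity
#' threshold (`cfg$nmj_threshold_method`, computed on the whole volume),
#' then per-slice binary erosion by a Euclidean disc of radius
#' `cfg$nmj_erosion_px`. Blur and erosion are applied slice-wise because
#' axial sampling is much coarser than lateral sampling.
#'
#' @param volume An [image_volume()].
#' @param cfg An [experiment_config()]; use
#'   `config_preset("fig9LN")` for the sigma-4 / erosion-1 / Otsu variant.
#' @param roles Channel roles entering the composite; defaults to
#'   `cfg$nmj_mask_roles` intersected with the available channels must be
#'   supplied explicitly for recipes lacking Brp.
#' @return A [mask_image()] (3D); provenance records every parameter.
#' @export
bouton_mask_3d <- function(volume, cfg = experiment_config(),
                           roles = cfg$nmj_mask_roles) {
  stopifnot(inherits(volume, "image_volume"))
  missing_roles <- setdiff(roles, names(volume$channels))
  if (length(missing_roles)) {
    stop("mask recipe channels absent: ",
         paste(missing_roles, collapse = ", "))
  }
  comp <- normalized_sum(volume$channels[roles])
  nz <- dim(comp)[3]
  for (z in seq_len(nz)) {
    comp[, , z] <- gauss_blur2d(comp[, , z], cfg$nmj_gaussian_sigma_px)
  }
  thr <- auto_threshold(comp, cfg$nmj_threshold_method)
  mask <- comp >= thr
  for (z in seq_len(nz)) {
    mask[, , z] <- binary_erode(mask[, , z], cfg$nmj_erosion_px)
  }
  if (!any(mask)) stop("empty mask after erosion")
  mask_image(mask, provenance = list(
    method = "normalized_sum+gaussian+threshold+erode",
    roles = roles, sigma = cfg$nmj_gaussian_sigma_px,
    threshold_method = cfg$nmj_threshold_method, threshold = thr,
    erosion_px = cfg$nmj_erosion_px))
}

#' Whole-bouton 3D intensity measurement
#'
#' Subtracts the rolling-ball background from every slice of every channel
#' (radius `cfg$rolling_ball_radius_px`), then reports the mean of each
#' channel within the 3D mask, plus the mask volume in pixels and
#' cubic micrometres (lateral^2 x axial calibration).
#'
#' @param volume An [image_volume()].
#' @param mask A 3D [mask_image()] from [bouton_mask_3d()].
#' @param cfg An [experiment_config()].
#' @return One-row data frame: `image_id`, `volume_px`, `volume_um3` and a
#'   `mean_<role>` column per channel.
#' @export
measure_bouton <- function(volume, mask, cfg = experiment_config()) {
  stopifnot(inherits(volume, "image_volume"))
  m <- mask_pixels(mask)
  if (!any(m)) stop("empty mask")
  cal <- volume$calibration
  vox_um3 <- cal$lateral_nm^2 * cal$axial_nm / 1e9
  out <- data.frame(image_id = volume$id, volume_px = sum(m),
                    volume_um3 = sum(m) * vox_um3)
  nz <- dim(m)[3]
  for (role in names(volume$channels)) {
    ch <- volume$channels[[role]]
    for (z in seq_len(nz)) {
      ch[, , z] <- rolling_ball_subtract(ch[, , z],
                                         cfg$rolling_ball_radius_px)
    }
    out[[paste0("mean_", role)]] <- mean(ch[m])
  }
  out
}
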
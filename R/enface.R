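#' En-face inclusion mask
#'
#' Binary mask of the vesicle-marker signal at or above `threshold`,
#' morphologically dilated by a Euclidean disc of radius
#' `cfg$enface_dilation_px`. Only protein objects inside this mask (i.e.
#' within the dilation margin of the vesicle cloud's edge) are analyzed.
#' At 22.7 nm pixels the default 6-pixel dilation corresponds to a margin
#' of 136 nm (truncated to integer nm).
#'
#' @param vesicle_channel 2D numeric matrix.
#' @param threshold Positive intensity threshold.
#' @param cfg An [experiment_config()].
#' @return A [mask_image()]; provenance records threshold and radius.
#' @export
build_inclusion_mask <- function(vesicle_channel, threshold,
                                 cfg = experiment_config()) {
  stopifnot(is.matrix(vesicle_channel), threshold > 0)
  core <- vesicle_channel >= threshold
  if (!any(core)) stop("empty mask after thresholding")
  r <- cfg$enface_dilation_px
  mask_image(binary_dilate(core, r),
             provenance = list(method = "threshold+dilate",
                               threshold = threshold, dilation_px = r))
}

#' Detect protein clusters at an en-face synapse
#'
#' Objects are 8-connected components of `channel >= threshold` within the
#' inclusion mask, of at least `cfg$min_size_px` pixels. Intensities are
#' measured on the original, non-thresholded image; each record carries its
#' area, geometric centroid, mean and integrated intensity (area times
#' mean) and the distance from its centroid to the active-zone center.
#' When `cfg$distance_band_nm` is set, only clusters whose center distance
#' falls inside the band are kept.
#'
#' @param channel 2D numeric matrix (protein of interest).
#' @param threshold Intensity threshold.
#' @param inclusion A [mask_image()] from [build_inclusion_mask()].
#' @param az_center Length-2 numeric `c(x, y)` in nm (e.g. from
#'   [az_center_nm()]).
#' @param cal A [pixel_calibration()].
#' @param cfg An [experiment_config()].
#' @return A data frame of cluster records (possibly 0 rows): `label`,
#'   `area_px`, `area_nm2`, `centroid_x_nm`, `centroid_y_nm`,
#'   `mean_intensity`, `integrated_intensity`, `distance_nm`.
#' @export
detect_clusters <- function(channel, threshold, inclusion, az_center, cal,
                            cfg = experiment_config()) {
  stopifnot(is.matrix(channel), inherits(cal, "pixel_calibration"))
  inc <- mask_pixels(inclusion)
  if (!any(inc)) stop("inclusion mask is empty")
  bw <- (channel >= threshold) & inc
  lab <- label_components(bw)
  n <- max(lab)
  nm <- cal$lateral_nm
  rows <- list()
  for (id in seq_len(n)) {
    coords <- which(lab == id, arr.ind = TRUE)
    if (nrow(coords) < cfg$min_size_px) next
    vals <- channel[coords]
    cx <- (mean(coords[, 2]) - 1 + 0.5) * nm
    cy <- (mean(coords[, 1]) - 1 + 0.5) * nm
    m <- mean(vals)
    d <- sqrt((cx - az_center[1])^2 + (cy - az_center[2])^2)
    rows[[length(rows) + 1L]] <-
      data.frame(label = id, area_px = nrow(coords),
                 area_nm2 = nrow(coords) * nm^2,
                 centroid_x_nm = cx, centroid_y_nm = cy,
                 mean_intensity = m,
                 integrated_intensity = nrow(coords) * m,
                 distance_nm = d)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(0), area_px = integer(0),
               area_nm2 = numeric(0), centroid_x_nm = numeric(0),
               centroid_y_nm = numeric(0), mean_intensity = numeric(0),
               integrated_intensity = numeric(0), distance_nm = numeric(0))
  if (!is.null(cfg$distance_band_nm) && nrow(out)) {
    b <- cfg$distance_band_nm
    out <- out[out$distance_nm >= b[1] & out$distance_nm <= b[2], ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Active-zone center of an en-face synapse
#'
#' Intensity-weighted centroid (nm) of the thresholded marker object nearest
#' to the given approximate center.
#'
#' @param marker_channel 2D numeric matrix.
#' @param threshold Intensity threshold.
#' @param cal A [pixel_calibration()].
#' @param near_px Optional approximate center `c(x, y)` in 0-based pixels;
#'   defaults to the brightest marker pixel.
#' @return Length-2 numeric `c(x, y)` in nm.
#' @export
az_center_nm <- function(marker_channel, threshold, cal, near_px = NULL) {
  bw <- marker_channel >= threshold
  if (!any(bw)) stop("no marker object above threshold")
  lab <- label_components(bw)
  if (is.null(near_px)) {
    i <- which.max(marker_channel * bw)
    near_px <- c((i - 1) %/% nrow(marker_channel),
                 (i - 1) %% nrow(marker_channel))  # (x, y)
  }
  fg <- which(lab > 0, arr.ind = TRUE)
  d2 <- (fg[, 2] - 1 - near_px[1])^2 + (fg[, 1] - 1 - near_px[2])^2
  id <- lab[fg[which.min(d2), , drop = FALSE]]
  coords <- which(lab == id, arr.ind = TRUE)
  wts <- marker_channel[coords]
  nm <- cal$lateral_nm
  c(x = (sum((coords[, 2] - 1) * wts) / sum(wts) + 0.5) * nm,
    y = (sum((coords[, 1] - 1) * wts) / sum(wts) + 0.5) * nm)
}

#' Per-synapse summary of en-face clusters
#'
#' @param clusters A cluster data frame from [detect_clusters()].
#' @return One-row data frame: `n_objects`, `mean_distance_nm`,
#'   `mean_integrated_intensity`, `total_integrated_intensity` (means are
#'   `NA` for empty cluster lists).
#' @export
enface_summary <- function(clusters) {
  n <- nrow(clusters)
  data.frame(
    n_objects = n,
    mean_distance_nm = if (n) mean(clusters$distance_nm) else NA_real_,
    mean_integrated_intensity =
      if (n) mean(clusters$integrated_intensity) else NA_real_,
    total_integrated_intensity =
      if (n) sum(clusters$integrated_intensity) else 0
  )
}
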
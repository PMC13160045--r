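#' Experiment configuration
#'
#' A single validated container for every tunable parameter of the analysis
#' stages. Each stage reads its parameters only from here, so a run is fully
#' described by one config (plus the input images).
#'
#' The defaults reproduce the standard workflow: a 750 nm profile window
#' smoothed with a 5-pixel rolled average, a symmetric 68 nm-per-side
#' periactive-zone window (or a one-sided 136 nm window toward the
#' presynaptic bouton), a 6-pixel en-face inclusion dilation, a 250 nm
#' minimum vesicle-cloud extent for side-view screening, NMJ mask building
#' with a sigma = 5 px gaussian, automatic thresholding and 4 px erosion,
#' rolling-ball background subtraction with radius 50 px, edge exclusion at
#' a mean Euclidean-distance-map score of 7.5 px, a 175 nm mesh band and
#' base-2 log polarization.
#'
#' @param profile_length_nm Length of the side-view profile window (nm).
#' @param rolled_average_px Width of the centered rolled average applied to
#'   each profile channel (samples).
#' @param window_mode `"symmetric_68"` (max within 68 nm each side of the
#'   marker peak) or `"onesided_136"` (max within 136 nm toward the
#'   presynaptic side).
#' @param window_halfwidth_nm Half-width of the symmetric window (nm).
#' @param window_onesided_nm Extent of the one-sided window (nm).
#' @param enface_dilation_px Dilation radius of the en-face inclusion mask.
#' @param roi_extra_width_px Extra profile width on each side of the marker.
#' @param sideview_min_cloud_nm Minimum vesicle-cloud extent for acceptance.
#' @param bar_elongation_min Minimum marker second-moment axis ratio for a
#'   "bar-like" side-view marker.
#' @param min_size_px Minimum object size (pixels) for cluster detection.
#' @param nmj_gaussian_sigma_px Gaussian sigma for the NMJ mask composite.
#' @param nmj_threshold_method One of `"otsu"`, `"li"`, `"triangle"`,
#'   `"isodata"`.
#' @param nmj_erosion_px Binary erosion radius applied to the NMJ mask.
#' @param nmj_mask_roles Channel roles combined into the 3D mask composite.
#' @param rolling_ball_radius_px Radius of the rolling-ball background.
#' @param edm_edge_cutoff_px Units with mean EDM below this are edge-excluded.
#' @param mesh_width_nm Width of the periactive-zone mesh band.
#' @param polarization_log_base Base of the mesh/core log ratio.
#' @param sigma_seed_px Light smoothing applied before minima detection.
#' @param k_h Multiplier of the robust spread (MAD) setting the minima
#'   suppression depth.
#' @param min_pak_px Minimum thresholded Pak pixels for apposition.
#' @param distance_band_nm Optional length-2 numeric: keep only en-face
#'   clusters whose center distance falls in this band (nm). `NULL` = off.
#' @param channel_thresholds Named numeric vector of fixed per-role
#'   intensity thresholds (set per experiment; `NA`/missing roles fall back
#'   to automatic Otsu thresholds, intended for synthetic data).
#' @param upper_half Which half of a z-stack is the "upper" (surface) half
#'   when projecting: `"first"` or `"last"`.
#' @param rng_seed Integer seed consumed by all stochastic operations.
#' @return An object of class `experiment_config` (a validated named list).
#' @seealso [config_preset()]
#' @export
experiment_config <- function(profile_length_nm = 750,
                              rolled_average_px = 5L,
                              window_mode = c("symmetric_68", "onesided_136"),
                              window_halfwidth_nm = 68,
                              window_onesided_nm = 136,
                              enface_dilation_px = 6L,
                              roi_extra_width_px = 5L,
                              sideview_min_cloud_nm = 250,
                              bar_elongation_min = 2.0,
                              min_size_px = 1L,
                              nmj_gaussian_sigma_px = 5,
                              nmj_threshold_method = c("li", "otsu",
                                                       "triangle", "isodata"),
                              nmj_erosion_px = 4L,
                              nmj_mask_roles = c("nwk", "dyn", "brp"),
                              rolling_ball_radius_px = 50L,
                              edm_edge_cutoff_px = 7.5,
                              mesh_width_nm = 175,
                              polarization_log_base = 2,
                              sigma_seed_px = 2,
                              k_h = 0.5,
                              min_pak_px = 1L,
                              distance_band_nm = NULL,
                              channel_thresholds = NULL,
                              upper_half = c("first", "last"),
                              rng_seed = 1L) {
  window_mode <- match.arg(window_mode)
  nmj_threshold_method <- match.arg(nmj_threshold_method)
  upper_half <- match.arg(upper_half)
  cfg <- list(
    profile_length_nm = profile_length_nm,
    rolled_average_px = as.integer(rolled_average_px),
    window_mode = window_mode,
    window_halfwidth_nm = window_halfwidth_nm,
    window_onesided_nm = window_onesided_nm,
    enface_dilation_px = as.integer(enface_dilation_px),
    roi_extra_width_px = as.integer(roi_extra_width_px),
    sideview_min_cloud_nm = sideview_min_cloud_nm,
    bar_elongation_min = bar_elongation_min,
    min_size_px = as.integer(min_size_px),
    nmj_gaussian_sigma_px = nmj_gaussian_sigma_px,
    nmj_threshold_method = nmj_threshold_method,
    nmj_erosion_px = as.integer(nmj_erosion_px),
    nmj_mask_roles = nmj_mask_roles,
    rolling_ball_radius_px = as.integer(rolling_ball_radius_px),
    edm_edge_cutoff_px = edm_edge_cutoff_px,
    mesh_width_nm = mesh_width_nm,
    polarization_log_base = polarization_log_base,
    sigma_seed_px = sigma_seed_px,
    k_h = k_h,
    min_pak_px = as.integer(min_pak_px),
    distance_band_nm = distance_band_nm,
    channel_thresholds = channel_thresholds,
    upper_half = upper_half,
    rng_seed = as.integer(rng_seed)
  )
  validate_config(cfg)
  structure(cfg, class = "experiment_config")
}

validate_config <- function(cfg) {
  pos <- c("profile_length_nm", "rolled_average_px", "window_halfwidth_nm",
           "window_onesided_nm", "roi_extra_width_px", "sideview_min_cloud_nm",
           "bar_elongation_min", "min_size_px", "nmj_gaussian_sigma_px",
           "rolling_ball_radius_px", "edm_edge_cutoff_px", "mesh_width_nm",
           "polarization_log_base", "sigma_seed_px", "k_h", "min_pak_px")
  for (nm in pos) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("config parameter '", nm, "' must be a single positive number")
    }
  }
  for (nm in c("enface_dilation_px", "nmj_erosion_px")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v < 0) {
      stop("config parameter '", nm, "' must be a single non-negative number")
    }
  }
  if (!is.null(cfg$distance_band_nm)) {
    b <- cfg$distance_band_nm
    if (length(b) != 2L || b[1] < 0 || b[2] <= b[1]) {
      stop("distance_band_nm must be an increasing length-2 band")
    }
  }
  invisible(cfg)
}

#' Named configuration presets
#'
#' `"default_nmj"` is the standard NMJ mask recipe (gaussian sigma 5, erosion
#' 4 px, automatic "li" thresholding); `"fig9LN"` is the variant used for the
#' Brp/Pak/FasII triple stain (sigma 4, erosion 1, Otsu thresholding). The
#' two presets differ only in those three fields.
#'
#' @param name Preset name.
#' @param ... Further overrides passed to [experiment_config()].
#' @return An `experiment_config`.
#' @export
config_preset <- function(name = c("default_nmj", "fig9LN"), ...) {
  name <- match.arg(name)
  switch(name,
    default_nmj = experiment_config(...),
    fig9LN = experiment_config(nmj_gaussian_sigma_px = 4,
                               nmj_erosion_px = 1L,
                               nmj_threshold_method = "otsu", ...)
  )
}

#' Read or write a configuration as YAML
#'
#' The on-disk dialect is plain YAML 1.1 (one document, scalar and sequence
#' values only).
#'
#' @param path File path.
#' @param cfg An `experiment_config`.
#' @return `read_config()` returns an `experiment_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(experiment_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$channel_thresholds)) {
    raw$channel_thresholds <- unlist(raw$channel_thresholds)
  }
  do.call(experiment_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "experiment_config"))
  x <- unclass(cfg)
  x$channel_thresholds <- as.list(x$channel_thresholds)
  yaml::write_yaml(x, path)
  invisible(path)
}
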
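#' Side-view synapse region of interest
#'
#' A rectangular profile window drawn across the center of a bar-like
#' active-zone (or postsynaptic) marker, perpendicular to the bar. The
#' profile axis points toward the presynaptic side when multiplied by
#' `presynaptic_sign`.
#'
#' @param center_px Length-2 numeric `c(x, y)`, 0-based pixel coordinates of
#'   the marker-bar center.
#' @param angle Profile-axis direction in radians, in `[0, pi)`.
#' @param width_px Averaging width in pixels (marker width plus up to
#'   `roi_extra_width_px` on each side), `>= 1`.
#' @param length_nm Profile length (defaults to the config value at
#'   extraction time).
#' @param presynaptic_sign `+1` if the positive axis direction points into
#'   the presynaptic bouton, else `-1`.
#' @return A `sideview_roi` object.
#' @export
sideview_roi <- function(center_px, angle, width_px, length_nm = NULL,
                         presynaptic_sign = 1L) {
  stopifnot(length(center_px) == 2L, is.finite(angle),
            width_px >= 1, presynaptic_sign %in% c(-1L, 1L))
  angle <- angle %% pi
  structure(list(center_px = c(x = unname(center_px[1]),
                               y = unname(center_px[2])),
                 angle = angle, width_px = as.integer(round(width_px)),
                 length_nm = length_nm,
                 presynaptic_sign = as.integer(presynaptic_sign)),
            class = "sideview_roi")
}

# Bilinear interpolation of matrix `m` ([y, x]) at 0-based coordinates.
bilinear <- function(m, x, y) {
  nx <- ncol(m); ny <- nrow(m)
  if (any(x < 0 | x > nx - 1 | y < 0 | y > ny - 1)) {
    stop("roi exceeds image bounds")
  }
  x0 <- pmin(floor(x), nx - 2); y0 <- pmin(floor(y), ny - 2)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x0 + 2)
  i10 <- cbind(y0 + 2, x0 + 1); i11 <- cbind(y0 + 2, x0 + 2)
  m[i00] * (1 - fx) * (1 - fy) + m[i01] * fx * (1 - fy) +
    m[i10] * (1 - fx) * fy + m[i11] * fx * fy
}

# Centered moving average of width w with shrink-to-valid-window edges.
rolled_average <- function(v, w) {
  if (w <= 1) return(v)
  h <- (w - 1) %/% 2
  n <- length(v)
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Extract a smoothed line profile across a side-view synapse
#'
#' Samples every channel along the ROI axis at one lateral-pixel spacing,
#' averaging across the ROI width with bilinear sub-pixel interpolation,
#' then applies the centered rolled average (`cfg$rolled_average_px`
#' samples, window shrunk at the profile ends). Positions are nm relative
#' to the ROI center; [align_profile()] / [align_and_average()] move the
#' origin to the reference-marker peak.
#'
#' @param field An [image_field()].
#' @param roi A [sideview_roi()].
#' @param cfg An [experiment_config()].
#' @return A `line_profile`: positions (nm), per-channel intensities,
#'   smoothing record, reference role and presynaptic sign.
#' @export
extract_profile <- function(field, roi, cfg = experiment_config()) {
  stopifnot(inherits(field, "image_field"), inherits(roi, "sideview_roi"))
  ref <- intersect(c("az_marker", "psd_marker"), names(field$channels))
  if (!length(ref)) stop("reference channel (az_marker or psd_marker) absent")
  ref <- ref[1]
  nm <- field$calibration$lateral_nm
  len <- roi$length_nm %||% cfg$profile_length_nm
  half_k <- floor((len / 2) / nm)
  tpos <- (-half_k:half_k) * nm
  u <- c(cos(roi$angle), sin(roi$angle))
  v <- c(-sin(roi$angle), cos(roi$angle))
  woff <- seq_len(roi$width_px) - (roi$width_px + 1) / 2
  xs <- outer(tpos / nm, rep(u[1], length(woff))) +
    outer(rep(1, length(tpos)), woff * v[1]) + roi$center_px["x"]
  ys <- outer(tpos / nm, rep(u[2], length(woff))) +
    outer(rep(1, length(tpos)), woff * v[2]) + roi$center_px["y"]
  intensities <- lapply(field$channels, function(ch) {
    vals <- matrix(bilinear(ch, as.vector(xs), as.vector(ys)), nrow(xs))
    rolled_average(rowMeans(vals), cfg$rolled_average_px)
  })
  structure(list(positions_nm = tpos, intensities = intensities,
                 spacing_nm = nm, reference_role = ref,
                 presynaptic_sign = roi$presynaptic_sign,
                 smoothing = list(rolled_average_px = cfg$rolled_average_px),
                 aligned = FALSE),
            class = "line_profile")
}

#' Construct a line profile from traces
#'
#' Builds a `line_profile` from explicit position/intensity vectors, e.g.
#' for simulated traces that did not come from an image.
#'
#' @param positions_nm Uniformly spaced positions in nm.
#' @param intensities Named list of per-channel intensity vectors (same
#'   length as `positions_nm`); must include the reference role.
#' @param reference_role `"az_marker"` or `"psd_marker"`.
#' @param presynaptic_sign `+1` or `-1`.
#' @return A `line_profile`.
#' @export
line_profile <- function(positions_nm, intensities,
                         reference_role = "az_marker",
                         presynaptic_sign = 1L) {
  stopifnot(is.list(intensities), length(intensities) >= 1L,
            reference_role %in% names(intensities))
  sp <- unique(round(diff(positions_nm), 9))
  if (length(sp) != 1L) stop("positions must be uniformly spaced")
  lens <- vapply(intensities, length, integer(1))
  stopifnot(all(lens == length(positions_nm)))
  structure(list(positions_nm = positions_nm, intensities = intensities,
                 spacing_nm = sp, reference_role = reference_role,
                 presynaptic_sign = as.integer(presynaptic_sign),
                 smoothing = list(rolled_average_px = 1L), aligned = FALSE),
            class = "line_profile")
}

# Argmax with the deterministic tie-break: highest value, then position
# closest to 0, then the more presynaptic position.
profile_argmax <- function(values, positions, presyn_sign = 1L) {
  mx <- max(values)
  idx <- which(values >= mx - 1e-12 * max(abs(mx), 1))
  if (length(idx) > 1L) {
    d <- abs(positions[idx])
    idx <- idx[d == min(d)]
    if (length(idx) > 1L) {
      s <- presyn_sign * positions[idx]
      idx <- idx[which.max(s)]
    }
  }
  idx[1]
}

#' Align a profile to its reference-marker peak
#'
#' Shifts positions so the reference channel's argmax sits at 0. Errors if
#' the reference channel is flat (no unique peak and no tie-break applies).
#'
#' @param profile A `line_profile`.
#' @return The aligned `line_profile`.
#' @export
align_profile <- function(profile) {
  ref <- profile$intensities[[profile$reference_role]]
  if (diff(range(ref)) == 0) {
    stop("reference channel is flat; cannot align")
  }
  i <- profile_argmax(ref, profile$positions_nm, profile$presynaptic_sign)
  profile$positions_nm <- profile$positions_nm - profile$positions_nm[i]
  profile$aligned <- TRUE
  profile
}

#' Average aligned profiles and normalize to a reference mean
#'
#' Each profile is aligned to its reference-marker peak, traces are averaged
#' pointwise on the common sample lattice (positions covered by at least one
#' profile; the per-position profile count is recorded), and intensities are
#' divided by `reference_mean` and expressed in percent. Because individual
#' protein peaks are not always at the same position relative to the marker,
#' the maximum of the averaged protein trace is below the average of the
#' individual peak values.
#'
#' @param profiles List of `line_profile` objects with a common sample
#'   spacing.
#' @param reference_mean Positive normalization constant (average signal of
#'   the comparison condition, in the same intensity units).
#' @return An averaged `line_profile` in percent, with an `n_per_position`
#'   field.
#' @export
align_and_average <- function(profiles, reference_mean) {
  stopifnot(length(profiles) >= 1L, reference_mean > 0)
  aligned <- lapply(profiles, function(p) if (p$aligned) p else
    align_profile(p))
  sp <- aligned[[1]]$spacing_nm
  keys <- lapply(aligned, function(p) as.integer(round(p$positions_nm / sp)))
  grid <- sort(unique(unlist(keys)))
  roles <- names(aligned[[1]]$intensities)
  sums <- matrix(0, length(grid), length(roles),
                 dimnames = list(NULL, roles))
  n <- integer(length(grid))
  for (i in seq_along(aligned)) {
    at <- match(keys[[i]], grid)
    n[at] <- n[at] + 1L
    for (role in roles) {
      sums[at, role] <- sums[at, role] + aligned[[i]]$intensities[[role]]
    }
  }
  means <- sums / n * 100 / reference_mean
  structure(list(positions_nm = grid * sp,
                 intensities = lapply(stats::setNames(roles, roles),
                                      function(r) means[, r]),
                 spacing_nm = sp,
                 reference_role = aligned[[1]]$reference_role,
                 presynaptic_sign = aligned[[1]]$presynaptic_sign,
                 smoothing = aligned[[1]]$smoothing,
                 aligned = TRUE, n_per_position = n, units = "percent"),
            class = "line_profile")
}

#' Peak metrics of an aligned profile
#'
#' `peak_to_peak_nm` is the signed position of the protein-of-interest
#' argmax relative to the reference peak (positive toward the presynaptic
#' side). `window_peak` is the maximum protein value within the
#' periactive-zone window: `[-68, +68]` nm around the marker peak
#' (`symmetric_68`) or `[0, 136]` nm toward the presynaptic side
#' (`onesided_136`), endpoints inclusive.
#'
#' @param profile An aligned `line_profile`.
#' @param cfg An [experiment_config()].
#' @return A `profile_summary` list: `peak_to_peak_nm`, `window_peak`,
#'   `window_mode`.
#' @export
profile_metrics <- function(profile, cfg = experiment_config()) {
  stopifnot(inherits(profile, "line_profile"))
  if (!isTRUE(profile$aligned)) stop("profile must be aligned first")
  pos <- profile$positions_nm
  prot <- profile$intensities[["protein_of_interest"]]
  if (is.null(prot)) stop("protein_of_interest channel absent")
  sgn <- profile$presynaptic_sign
  ptp <- pos[profile_argmax(prot, pos, sgn)] * sgn
  eps <- 1e-9
  if (cfg$window_mode == "symmetric_68") {
    w <- cfg$window_halfwidth_nm
    if (min(pos) > -w || max(pos) < w) stop("window extends past profile ends")
    inwin <- abs(pos) <= w + eps
  } else {
    w <- cfg$window_onesided_nm
    ppos <- sgn * pos
    if (max(ppos) < w) stop("window extends past profile ends")
    inwin <- ppos >= -eps & ppos <= w + eps
  }
  structure(list(peak_to_peak_nm = ptp, window_peak = max(prot[inwin]),
                 window_mode = cfg$window_mode),
            class = "profile_summary")
}

#' Geometric screen for side-view synapses
#'
#' Accepts a candidate ROI iff (a) the thresholded vesicle signal extends at
#' least `cfg$sideview_min_cloud_nm` from the marker toward the presynaptic
#' side along the profile axis, and (b) the thresholded marker object is
#' bar-like: its second-moment major/minor axis ratio is at least
#' `cfg$bar_elongation_min`. Fixed per-role thresholds come from
#' `cfg$channel_thresholds`; missing roles fall back to a whole-field Otsu
#' threshold.
#'
#' @param field An [image_field()] with vesicle and reference channels.
#' @param candidate A [sideview_roi()].
#' @param cfg An [experiment_config()].
#' @return A list: `accept` (logical), `reasons` (character), plus the
#'   measured `elongation` and `cloud_extent_nm`.
#' @export
screen_sideview <- function(field, candidate, cfg = experiment_config()) {
  ref <- intersect(c("az_marker", "psd_marker"), names(field$channels))[1]
  if (is.na(ref)) stop("reference channel absent")
  ves <- get_channel(field, "vesicle_marker")
  mk <- get_channel(field, ref)
  thr_mk <- role_threshold(cfg, ref, mk)
  thr_ves <- role_threshold(cfg, "vesicle_marker", ves)
  lab <- label_components(mk >= thr_mk)
  cx <- candidate$center_px["x"]; cy <- candidate$center_px["y"]
  # marker object at (or nearest to, within 5 px of) the candidate center
  obj <- 0L
  if (lab[round(cy) + 1, round(cx) + 1] > 0) {
    obj <- lab[round(cy) + 1, round(cx) + 1]
  } else {
    fg <- which(lab > 0, arr.ind = TRUE)
    if (nrow(fg)) {
      d2 <- (fg[, 1] - 1 - cy)^2 + (fg[, 2] - 1 - cx)^2
      if (min(d2) <= 25) obj <- lab[fg[which.min(d2), , drop = FALSE]]
    }
  }
  if (obj == 0L) stop("no marker object above threshold at the candidate")
  coords <- which(lab == obj, arr.ind = TRUE)
  elong <- if (nrow(coords) < 3) 1 else {
    ev <- eigen(stats::cov(coords[, c(2, 1)]), symmetric = TRUE,
                only.values = TRUE)$values
    sqrt(max(ev[1], 1e-12) / max(ev[2], 1e-12))
  }
  # vesicle extent along the presynaptic direction
  nm <- field$calibration$lateral_nm
  sgn <- candidate$presynaptic_sign
  len <- (candidate$length_nm %||% cfg$profile_length_nm) / 2
  tq <- seq(0, len, by = nm)
  u <- c(cos(candidate$angle), sin(candidate$angle)) * sgn
  vx <- cx + tq / nm * u[1]
  vy <- cy + tq / nm * u[2]
  inb <- vx >= 0 & vx <= ncol(ves) - 1 & vy >= 0 & vy <= nrow(ves) - 1
  vals <- rep(0, length(tq))
  vals[inb] <- bilinear(ves, vx[inb], vy[inb])
  above <- vals >= thr_ves
  extent <- 0
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    # the run containing the largest vesicle value on the presynaptic side
    peak_i <- which.max(vals)
    kr <- runs[starts[runs] <= peak_i & ends[runs] >= peak_i]
    if (length(kr)) {
      extent <- tq[ends[kr[1]]]
    }
  }
  reasons <- character(0)
  if (extent < cfg$sideview_min_cloud_nm) {
    reasons <- c(reasons, sprintf("cloud < %g nm", cfg$sideview_min_cloud_nm))
  }
  if (elong < cfg$bar_elongation_min) {
    reasons <- c(reasons, "marker not bar-like")
  }
  list(accept = length(reasons) == 0L, reasons = reasons,
       elongation = elong, cloud_extent_nm = extent)
}

role_threshold <- function(cfg, role, channel) {
  thr <- cfg$channel_thresholds[[role]]
  if (is.null(thr) || is.na(thr)) thr <- auto_threshold(channel, "otsu")
  thr
}

#' Build side-view ROIs from a synthetic ground truth
#'
#' Convenience for parameter-recovery runs: converts the generator's
#' side-view synapse records into [sideview_roi()] objects, using the
#' recorded axis angle and sign convention and a width of the marker-bar
#' width plus `cfg$roi_extra_width_px` on each side.
#'
#' @param truth A `ground_truth` from [generate_sted_field()].
#' @param cfg An [experiment_config()].
#' @return List of `sideview_roi`.
#' @export
sideview_rois_from_truth <- function(truth, cfg = experiment_config()) {
  stopifnot(identical(truth$kind, "sted"))
  cal <- pixel_calibration(truth$params$lateral_nm)
  wpx <- nm_to_px(truth$params$marker_width_nm, cal) +
    2L * cfg$roi_extra_width_px
  sv <- Filter(function(s) s$type == "sideview", truth$synapses)
  lapply(sv, function(s) {
    sideview_roi(s$center_px, s$angle, width_px = wpx,
                 presynaptic_sign = s$presynaptic_sign)
  })
}
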
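#' Maximum projection of the upper half of a z-stack
#'
#' Projects the half of the stack facing the objective to analyze a single
#' plasma-membrane surface. For odd Z the middle slice is included. Which
#' end of the stack is "upper" is a configuration flag (`cfg$upper_half`,
#' default the first half), never assumed silently for real data.
#'
#' @param volume An [image_volume()].
#' @param cfg An [experiment_config()].
#' @return An [image_field()] of per-channel maxima with the lateral
#'   calibration.
#' @export
upper_half_projection <- function(volume, cfg = experiment_config()) {
  stopifnot(inherits(volume, "image_volume"))
  nz <- dim(volume$channels[[1]])[3]
  n <- ceiling(nz / 2)
  slices <- if (cfg$upper_half == "first") seq_len(n) else (nz - n + 1):nz
  chans <- lapply(volume$channels, function(ch) {
    apply(ch[, , slices, drop = FALSE], c(1, 2), max)
  })
  image_field(chans, pixel_calibration(volume$calibration$lateral_nm),
              id = volume$id)
}

#' Total presynaptic-area mask of a projection
#'
#' Auto-thresholds the plain sum of all channels.
#'
#' @param field An [image_field()].
#' @param cfg An [experiment_config()] (`nmj_threshold_method`).
#' @return A [mask_image()].
#' @export
total_mask_2d <- function(field, cfg = experiment_config()) {
  s <- Reduce(`+`, field$channels)
  thr <- auto_threshold(s, cfg$nmj_threshold_method)
  mask_image(s >= thr,
             provenance = list(method = "sum+threshold",
                               threshold_method = cfg$nmj_threshold_method,
                               threshold = thr))
}

#' Composite recipe for periactive-zone segmentation
#'
#' The segmentation composite is a sum of the periactive-zone channels minus
#' the channels marking other compartments, each mean-normalized first
#' (default on) and clamped at zero (default on). Presets: `"default"`
#' (Nwk + Dyn - Brp), `"fig6_nwk_only"` (Nwk only, no Brp staining) and
#' `"fig9_fasII"` (FasII - Brp - Pak).
#'
#' @param positive,negative Character vectors of channel roles.
#' @param normalize Mean-normalize each channel before combining?
#' @param clamp Clamp the composite at zero?
#' @return A `composite_recipe` object.
#' @export
composite_recipe <- function(positive, negative = character(0),
                             normalize = TRUE, clamp = TRUE) {
  stopifnot(length(positive) >= 1L)
  check_roles(c(positive, negative))
  structure(list(positive = positive, negative = negative,
                 normalize = normalize, clamp = clamp),
            class = "composite_recipe")
}

#' @rdname composite_recipe
#' @param name Preset name.
#' @export
composite_recipe_preset <- function(name = c("default", "fig6_nwk_only",
                                             "fig9_fasII")) {
  name <- match.arg(name)
  switch(name,
    default = composite_recipe(c("nwk", "dyn"), "brp"),
    fig6_nwk_only = composite_recipe("nwk"),
    fig9_fasII = composite_recipe("fasII", c("brp", "pak")))
}

#' Build the periactive-zone composite image
#'
#' @param field An [image_field()] containing the recipe roles.
#' @param recipe A [composite_recipe()].
#' @return Numeric matrix.
#' @export
paz_composite <- function(field, recipe) {
  stopifnot(inherits(field, "image_field"),
            inherits(recipe, "composite_recipe"))
  norm1 <- function(role, sign) {
    ch <- get_channel(field, role)
    if (recipe$normalize) {
      m <- mean(ch)
      if (m <= 0) stop("channel '", role, "' has zero mean")
      ch <- ch / m
    }
    sign * ch
  }
  out <- Reduce(`+`, c(lapply(recipe$positive, norm1, sign = 1),
                       lapply(recipe$negative, norm1, sign = -1)))
  if (recipe$clamp) out <- pmax(out, 0)
  out
}

#' Segment periactive-zone units by seeded region growing
#'
#' Seeds are the regional minima of the lightly smoothed composite
#' (`cfg$sigma_seed_px`), suppressed to a depth of `cfg$k_h` times the
#' median absolute deviation of the composite within the mask (an h-minima
#' transform implemented by morphological reconstruction). Each seed is then
#' expanded over the mask by seeded region growing in ascending raw
#' composite intensity with deterministic tie-breaking (lower intensity,
#' then lower seed label, then raster order), until every mask pixel is
#' labeled.
#'
#' @param composite Numeric matrix from [paz_composite()].
#' @param mask A [mask_image()] (or logical matrix) of the presynaptic area.
#' @param cfg An [experiment_config()].
#' @return A `paz_segmentation`: `labels` (integer matrix, 0 = background),
#'   `n_units`, `seeds` (label matrix of seed plateaus), `h`.
#' @export
segment_paz_units <- function(composite, mask, cfg = experiment_config()) {
  m <- mask_pixels(mask)
  stopifnot(identical(dim(composite), dim(m)))
  if (!any(m)) stop("mask is empty")
  if (diff(range(composite[m])) == 0) {
    stop("no seeds found: composite is flat within the mask")
  }
  # Masked (normalized) smoothing keeps the background from bleeding across
  # the mask border, which would otherwise carve spurious minima along the
  # bouton rim. The float32 snap removes FFT-level ripples on constant
  # plateaus, and the small floor on h guards the minima depth against
  # numerical noise when the robust spread collapses.
  sm <- snap_float32(gauss_blur2d_masked(composite, cfg$sigma_seed_px, m))
  h <- max(cfg$k_h * mad(composite[m], constant = 1),
           1e-6 * diff(range(composite[m])))
  if (h > 0) {
    sm <- cpp_reconstruct_erode(sm + h, sm, m)
  }
  seeds <- cpp_regional_minima(sm, m)
  n <- max(seeds)
  if (n == 0L) stop("no seeds found")
  labels <- cpp_srg(composite, seeds, m)
  structure(list(labels = labels, n_units = n, seeds = seeds, h = h),
            class = "paz_segmentation")
}

#' Periactive-zone unit collection
#'
#' Bundles a label image with its mask and builds one record per unit.
#' [exclude_edge_units()], [split_mesh_core()], [polarization()] and
#' [classify_units()] operate on this collection.
#'
#' @param seg A `paz_segmentation` (or a plain integer label matrix).
#' @param mask The [mask_image()] the segmentation was grown in.
#' @return A `paz_units` object.
#' @export
paz_units <- function(seg, mask) {
  labels <- if (inherits(seg, "paz_segmentation")) seg$labels else seg
  m <- mask_pixels(mask)
  n <- max(labels)
  units <- lapply(seq_len(n), function(id) {
    idx <- which(labels == id)
    list(id = id, idx = idx, n_px = length(idx))
  })
  structure(list(labels = labels, mask = m, units = units), class = "paz_units")
}

#' @export
print.paz_units <- function(x, ...) {
  n_edge <- sum(vapply(x$units, function(u) isTRUE(u$edge_excluded),
                       logical(1)))
  cat("paz_units:", length(x$units), "units,", n_edge, "edge-excluded\n")
  invisible(x)
}

#' Flag units at the bouton edge
#'
#' Computes the Euclidean distance map of the mask (distance of each
#' foreground pixel to the nearest background pixel) and flags every unit
#' whose mean EDM score over its pixels is below `cfg$edm_edge_cutoff_px`;
#' such units sit at the bouton edge and are not planar, so they are
#' excluded from per-unit analyses.
#'
#' @param units A [paz_units()] collection.
#' @param cfg An [experiment_config()].
#' @return The collection with `mean_edm` and `edge_excluded` set per unit.
#' @export
exclude_edge_units <- function(units, cfg = experiment_config()) {
  stopifnot(inherits(units, "paz_units"))
  edm <- distance_map(units$mask)
  units$units <- lapply(units$units, function(u) {
    u$mean_edm <- mean(edm[u$idx])
    u$edge_excluded <- u$mean_edm < cfg$edm_edge_cutoff_px
    u
  })
  units
}

#' Split units into mesh band and core
#'
#' The mesh of a unit is the inward band of its pixels whose Euclidean
#' distance (pixel centers) to the unit's exterior — pixels of a different
#' label or background — is at most `nm_to_px(cfg$mesh_width_nm)`; the core
#' is the remainder. A 20 x 20 px unit with a 7 px mesh keeps a 6 x 6 core.
#' Units too narrow to retain a core are flagged (`core_empty`) and skipped
#' by [polarization()].
#'
#' @param units A [paz_units()] collection.
#' @param cal A [pixel_calibration()].
#' @param cfg An [experiment_config()].
#' @return The collection with `mesh_idx`, `core_idx` and `core_empty` set.
#' @export
split_mesh_core <- function(units, cal, cfg = experiment_config()) {
  stopifnot(inherits(units, "paz_units"))
  band_px <- nm_to_px(cfg$mesh_width_nm, cal)
  units$units <- lapply(units$units, function(u) {
    ub <- unit_band(units$labels, u$id, band_px)
    mesh_idx <- which(ub$band)
    u$mesh_idx <- mesh_idx
    u$core_idx <- setdiff(u$idx, mesh_idx)
    u$core_empty <- length(u$core_idx) == 0L
    u
  })
  units
}

#' Mesh/core polarization of a channel
#'
#' Log ratio (base `cfg$polarization_log_base`, default 2) of the mean
#' channel intensity within the mesh over the core of each analyzed unit.
#' Positive values indicate mesh enrichment, negative values core
#' enrichment. Undefined (returned as `NA`) for edge-excluded units, units
#' without a core, or non-positive mesh/core means.
#'
#' @param channel 2D numeric matrix.
#' @param units A [paz_units()] collection after [split_mesh_core()].
#' @param cfg An [experiment_config()].
#' @return Numeric vector, one value per unit.
#' @export
polarization <- function(channel, units, cfg = experiment_config()) {
  stopifnot(inherits(units, "paz_units"))
  vapply(units$units, function(u) {
    if (isTRUE(u$edge_excluded) || isTRUE(u$core_empty) ||
        is.null(u$mesh_idx)) {
      return(NA_real_)
    }
    mm <- mean(channel[u$mesh_idx])
    cm <- mean(channel[u$core_idx])
    if (!is.finite(mm) || !is.finite(cm) || mm <= 0 || cm <= 0) {
      return(NA_real_)
    }
    log(mm / cm, base = cfg$polarization_log_base)
  }, numeric(1))
}

#' Brp objects and their density
#'
#' Detects Brp objects as 8-connected components of the thresholded,
#' rolling-ball background-subtracted Brp projection within the mask
#' (minimum size `cfg$min_size_px`), and reports the object density per
#' square micrometre of masked NMJ area. Integrated intensity is area times
#' mean intensity on the background-subtracted projection. Objects are
#' assigned to the unit containing their centroid (0 = none); objects on
#' edge-excluded units still count toward whole-NMJ density.
#'
#' @param field An [image_field()] with a `brp` channel.
#' @param mask A [mask_image()] of the NMJ area.
#' @param cal A [pixel_calibration()].
#' @param cfg An [experiment_config()]; a fixed Brp threshold may be set in
#'   `cfg$channel_thresholds["brp"]`, otherwise Otsu is used.
#' @param labels Optional unit label matrix for ownership assignment.
#' @return A list: `objects` (data frame: `label`, `area_px`,
#'   `centroid_x_nm`, `centroid_y_nm`, `mean_intensity`,
#'   `integrated_intensity`, `unit_id`) and `density_per_um2`.
#' @export
brp_objects_and_density <- function(field, mask, cal,
                                    cfg = experiment_config(),
                                    labels = NULL) {
  brp <- get_channel(field, "brp")
  m <- mask_pixels(mask)
  if (!any(m)) stop("mask is empty")
  sub <- rolling_ball_subtract(brp, cfg$rolling_ball_radius_px)
  lab <- if (diff(range(sub)) == 0) {
    matrix(0L, nrow(sub), ncol(sub))  # featureless channel: no objects
  } else {
    thr <- role_threshold(cfg, "brp", sub)
    label_components((sub >= thr) & m)
  }
  nm <- cal$lateral_nm
  rows <- list()
  for (id in seq_len(max(lab))) {
    coords <- which(lab == id, arr.ind = TRUE)
    if (nrow(coords) < cfg$min_size_px) next
    vals <- sub[coords]
    cyx <- colMeans(coords)  # (row, col), 1-based
    unit_id <- if (!is.null(labels)) {
      labels[round(cyx[1]), round(cyx[2])]
    } else 0L
    rows[[length(rows) + 1L]] <- data.frame(
      label = id, area_px = nrow(coords),
      centroid_x_nm = (cyx[2] - 1 + 0.5) * nm,
      centroid_y_nm = (cyx[1] - 1 + 0.5) * nm,
      mean_intensity = mean(vals),
      integrated_intensity = nrow(coords) * mean(vals),
      unit_id = as.integer(unit_id))
  }
  objects <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(0), area_px = integer(0),
               centroid_x_nm = numeric(0), centroid_y_nm = numeric(0),
               mean_intensity = numeric(0),
               integrated_intensity = numeric(0), unit_id = integer(0))
  area_um2 <- sum(m) * nm^2 / 1e6
  list(objects = objects, density_per_um2 = nrow(objects) / area_um2)
}

#' Classify units as Brp-containing and Pak-apposed
#'
#' A unit is `brp_positive` iff at least one Brp object centroid lies inside
#' it, and `pak_apposed` iff at least `cfg$min_pak_px` thresholded Pak
#' pixels fall inside it. Percentages are computed over analyzed
#' (non-edge-excluded) units.
#'
#' @param units A [paz_units()] collection (after [exclude_edge_units()]).
#' @param brp_objects Object data frame from [brp_objects_and_density()]
#'   (with `unit_id`).
#' @param pak_channel 2D Pak matrix, or `NULL` to skip apposition.
#' @param cfg An [experiment_config()]; a fixed Pak threshold may be set in
#'   `cfg$channel_thresholds["pak"]`.
#' @return A list: `units` (the collection with flags),
#'   `pct_brp_positive`, `pct_pak_apposed` (over analyzed units).
#' @export
classify_units <- function(units, brp_objects, pak_channel = NULL,
                           cfg = experiment_config()) {
  stopifnot(inherits(units, "paz_units"))
  pak_bw <- NULL
  if (!is.null(pak_channel)) {
    thr <- role_threshold(cfg, "pak", pak_channel)
    pak_bw <- pak_channel >= thr
  }
  units$units <- lapply(units$units, function(u) {
    u$brp_positive <- u$id %in% brp_objects$unit_id
    u$pak_apposed <- if (is.null(pak_bw)) NA else
      sum(pak_bw[u$idx]) >= cfg$min_pak_px
    u
  })
  analyzed <- Filter(function(u) !isTRUE(u$edge_excluded), units$units)
  pct <- function(f) {
    v <- vapply(analyzed, f, logical(1))
    if (!length(v)) NA_real_ else 100 * mean(v, na.rm = TRUE)
  }
  list(units = units,
       pct_brp_positive = pct(function(u) isTRUE(u$brp_positive)),
       pct_pak_apposed = if (is.null(pak_bw)) NA_real_ else
         pct(function(u) isTRUE(u$pak_apposed)))
}

#' Full periactive-zone analysis of one NMJ volume
#'
#' Runs the complete pipeline: upper-half projection, total 2D mask,
#' composite, seeded-region-growing segmentation, edge exclusion, mesh/core
#' split, per-channel polarization, Brp objects/density and unit
#' classification.
#'
#' @param volume An [image_volume()].
#' @param cfg An [experiment_config()].
#' @param recipe A [composite_recipe()].
#' @param mesh_channels Channels to report mesh means and polarization for.
#' @return A list with `field`, `mask`, `segmentation`, `units`,
#'   `unit_table` (per-unit data frame), `brp` and `summary` (one-row
#'   data frame).
#' @export
analyze_nmj_paz <- function(volume, cfg = experiment_config(),
                            recipe = composite_recipe_preset("default"),
                            mesh_channels = intersect(
                              c("nwk", "dyn", "endoA", "dap160", "fasII"),
                              names(volume$channels))) {
  field <- upper_half_projection(volume, cfg)
  cal <- field$calibration
  mask <- total_mask_2d(field, cfg)
  comp <- paz_composite(field, recipe)
  seg <- segment_paz_units(comp, mask, cfg)
  pu <- paz_units(seg, mask)
  pu <- exclude_edge_units(pu, cfg)
  pu <- split_mesh_core(pu, cal, cfg)
  brp <- if ("brp" %in% names(field$channels)) {
    brp_objects_and_density(field, mask, cal, cfg, labels = seg$labels)
  } else NULL
  pak <- if ("pak" %in% names(field$channels)) {
    get_channel(field, "pak")
  } else NULL
  cls <- classify_units(pu, if (is.null(brp)) data.frame(unit_id = integer(0))
                        else brp$objects, pak, cfg)
  pu <- cls$units
  pol <- lapply(stats::setNames(mesh_channels, mesh_channels), function(r) {
    polarization(get_channel(field, r), pu, cfg)
  })
  unit_table <- do.call(rbind, lapply(pu$units, function(u) {
    row <- data.frame(image_id = volume$id, unit_id = u$id, n_px = u$n_px,
                      mean_edm = u$mean_edm, edge_excluded = u$edge_excluded,
                      core_empty = isTRUE(u$core_empty),
                      brp_positive = isTRUE(u$brp_positive),
                      pak_apposed = u$pak_apposed)
    for (r in mesh_channels) {
      ch <- get_channel(field, r)
      row[[paste0("mesh_mean_", r)]] <-
        if (length(u$mesh_idx)) mean(ch[u$mesh_idx]) else NA_real_
      row[[paste0("polarization_", r)]] <- pol[[r]][u$id]
    }
    row
  }))
  analyzed <- !unit_table$edge_excluded
  summary <- data.frame(
    image_id = volume$id,
    n_units_total = nrow(unit_table),
    n_units_analyzed = sum(analyzed),
    brp_density_per_um2 = if (is.null(brp)) NA_real_ else brp$density_per_um2,
    mean_brp_integrated = if (is.null(brp) || !nrow(brp$objects)) NA_real_
      else mean(brp$objects$integrated_intensity),
    pct_brp_positive = cls$pct_brp_positive,
    pct_pak_apposed = cls$pct_pak_apposed)
  for (r in mesh_channels) {
    summary[[paste0("mesh_mean_", r)]] <-
      mean(unit_table[[paste0("mesh_mean_", r)]][analyzed], na.rm = TRUE)
    summary[[paste0("polarization_", r)]] <-
      mean(unit_table[[paste0("polarization_", r)]][analyzed], na.rm = TRUE)
  }
  list(field = field, mask = mask, segmentation = seg, units = pu,
       unit_table = unit_table, brp = brp, summary = summary)
}
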
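#' Confocal presynaptic mask
#'
#' Otsu-thresholds the vesicle-marker channel to form a presynaptic mask and
#' removes user-supplied exclusion regions (somata, out-of-focus areas).
#'
#' @param field An [image_field()] with a `vesicle_marker` channel.
#' @param exclusions List of [mask_image()] objects (or logical matrices) to
#'   subtract.
#' @return A [mask_image()]; provenance records the threshold.
#' @export
presynaptic_mask <- function(field, exclusions = list()) {
  ves <- get_channel(field, "vesicle_marker")
  thr <- otsu_threshold(ves)
  mask <- ves >= thr
  for (ex in exclusions) {
    mask <- mask & !mask_pixels(ex)
  }
  if (!any(mask)) stop("empty mask after exclusion")
  mask_image(mask, provenance = list(method = "otsu", threshold = thr,
                                     n_exclusions = length(exclusions)))
}

#' Mean intensity within a mask
#'
#' @param channel 2D numeric matrix.
#' @param mask A [mask_image()] or logical matrix (non-empty).
#' @return Arithmetic mean of the channel over mask pixels.
#' @export
mean_in_mask <- function(channel, mask) {
  m <- mask_pixels(mask)
  stopifnot(identical(dim(channel), dim(m)))
  if (!any(m)) stop("empty mask")
  mean(channel[m])
}

#' Synaptic-level confocal summary of one image
#'
#' Builds the presynaptic mask and reports the mean intensity of every
#' channel within it, plus the per-object means averaged over the mask's
#' connected components (the pooled mean is the primary readout).
#'
#' @param field An [image_field()].
#' @param exclusions Optional exclusion masks.
#' @return One-row data frame: `image_id`, `mask_area_px`, and per-role
#'   `mean_<role>` / `objmean_<role>` columns.
#' @export
confocal_summary <- function(field, exclusions = list()) {
  mask <- presynaptic_mask(field, exclusions)
  m <- mask_pixels(mask)
  lab <- label_components(m)
  out <- data.frame(image_id = field$id, mask_area_px = sum(m))
  for (role in names(field$channels)) {
    ch <- field$channels[[role]]
    out[[paste0("mean_", role)]] <- mean(ch[m])
    per_obj <- vapply(seq_len(max(lab)),
                      function(id) mean(ch[lab == id]), numeric(1))
    out[[paste0("objmean_", role)]] <- mean(per_obj)
  }
  out
}
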
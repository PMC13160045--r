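#' Channel roles
#'
#' Channels are always addressed by biological role, never by acquisition
#' order; the role of each channel is declared when an image is constructed
#' or loaded. `channel_roles()` lists the recognized labels.
#'
#' @return Character vector of valid role names.
#' @export
channel_roles <- function() {
  c("vesicle_marker", "az_marker", "psd_marker", "protein_of_interest",
    "brp", "nwk", "dyn", "endoA", "dap160", "fasII", "pak", "other")
}

check_roles <- function(roles) {
  bad <- setdiff(roles, channel_roles())
  if (length(bad)) {
    stop("unknown channel role(s): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(roles)) {
    stop("each channel must map to exactly one role (duplicated roles found)")
  }
  invisible(roles)
}

check_intensities <- function(x, role) {
  if (!all(is.finite(x))) stop("channel '", role, "' has non-finite values")
  if (any(x < 0)) stop("channel '", role, "' has negative intensities")
  invisible(x)
}

#' Calibrated multi-channel images
#'
#' `image_field()` wraps 2D channels (matrices indexed `[y, x]`),
#' `image_volume()` wraps 3D channels (arrays indexed `[y, x, z]` with at
#' least two slices). All channels of one image share identical dimensions
#' and carry finite, non-negative intensities.
#'
#' @param channels Named list of numeric matrices (field) or 3D arrays
#'   (volume); names are channel roles, see [channel_roles()].
#' @param calibration A [pixel_calibration()]; volumes require an axial
#'   calibration.
#' @param id Optional source-image identifier carried into result tables.
#' @return An object of class `image_field` or `image_volume`.
#' @export
image_field <- function(channels, calibration, id = "field") {
  stopifnot(is.list(channels), length(channels) >= 1L,
            inherits(calibration, "pixel_calibration"))
  check_roles(names(channels))
  d <- dim(channels[[1]])
  if (length(d) != 2L) stop("image_field channels must be 2D matrices")
  for (role in names(channels)) {
    ch <- channels[[role]]
    if (!identical(dim(ch), d)) stop("all channels must share dimensions")
    check_intensities(ch, role)
  }
  structure(list(channels = channels, calibration = calibration, id = id),
            class = "image_field")
}

#' @rdname image_field
#' @export
image_volume <- function(channels, calibration, id = "volume") {
  stopifnot(is.list(channels), length(channels) >= 1L,
            inherits(calibration, "pixel_calibration"))
  check_roles(names(channels))
  d <- dim(channels[[1]])
  if (length(d) != 3L || d[3] < 2L) {
    stop("image_volume channels must be 3D arrays with Z >= 2")
  }
  if (is.null(calibration$axial_nm)) {
    stop("volumes require an axial calibration (nm/slice)")
  }
  for (role in names(channels)) {
    ch <- channels[[role]]
    if (!identical(dim(ch), d)) stop("all channels must share dimensions")
    check_intensities(ch, role)
  }
  structure(list(channels = channels, calibration = calibration, id = id),
            class = "image_volume")
}

#' @export
print.image_field <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("image_field '", x$id, "': ", d[2], " x ", d[1], " px, channels: ",
      paste(names(x$channels), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("image_volume '", x$id, "': ", d[2], " x ", d[1], " x ", d[3],
      " px, channels: ", paste(names(x$channels), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Fetch a channel by role
#'
#' @param img An `image_field` or `image_volume`.
#' @param role Channel role name.
#' @return The channel array.
#' @export
get_channel <- function(img, role) {
  ch <- img$channels[[role]]
  if (is.null(ch)) {
    stop("channel role '", role, "' not present (have: ",
         paste(names(img$channels), collapse = ", "), ")")
  }
  ch
}

#' Binary masks with provenance
#'
#' A mask is a logical array of the same shape as its source image, together
#' with a non-empty provenance record of the method and parameters that
#' produced it.
#'
#' @param pixels Logical (or 0/1 numeric) array.
#' @param provenance Named list describing how the mask was produced.
#' @return An object of class `mask_image`.
#' @export
mask_image <- function(pixels, provenance) {
  stopifnot(is.list(provenance), length(provenance) >= 1L)
  px <- pixels
  if (!is.logical(px)) {
    storage.mode(px) <- "logical"
  }
  if (anyNA(px)) stop("mask contains NA")
  structure(list(pixels = px, provenance = provenance), class = "mask_image")
}

#' @export
print.mask_image <- function(x, ...) {
  cat("mask_image: ", sum(x$pixels), "/", length(x$pixels),
      " foreground px; method: ",
      paste(x$provenance$method, collapse = "+"), "\n", sep = "")
  invisible(x)
}

mask_pixels <- function(mask) {
  if (inherits(mask, "mask_image")) mask$pixels else mask
}
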
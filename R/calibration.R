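#' Pixel calibration
#'
#' Physical size of a pixel (and, for volumes, of a z-step). All physical
#' distances reported by the package are in nanometres; the lateral
#' calibration is required for any physical-distance output. Pixel indices
#' are 0-based and the physical coordinate of a pixel center is
#' `(index + 0.5) * nm_per_px`.
#'
#' @param lateral_nm Lateral pixel pitch in nm/pixel (strictly positive).
#' @param axial_nm Axial step in nm/slice, or `NULL` for 2D data.
#' @return An object of class `pixel_calibration`.
#' @examples
#' cal <- pixel_calibration(22.7)
#' nm_to_px(136, cal)
#' @export
pixel_calibration <- function(lateral_nm, axial_nm = NULL) {
  if (!is.numeric(lateral_nm) || length(lateral_nm) != 1L ||
      !is.finite(lateral_nm) || lateral_nm <= 0) {
    stop("lateral calibration must be a single positive length (nm/px)")
  }
  if (!is.null(axial_nm)) {
    if (!is.numeric(axial_nm) || length(axial_nm) != 1L ||
        !is.finite(axial_nm) || axial_nm <= 0) {
      stop("axial calibration must be a single positive length (nm/slice)")
    }
  }
  structure(list(lateral_nm = lateral_nm, axial_nm = axial_nm),
            class = "pixel_calibration")
}

#' @export
print.pixel_calibration <- function(x, ...) {
  cat("pixel_calibration:", x$lateral_nm, "nm/px lateral")
  if (!is.null(x$axial_nm)) cat(",", x$axial_nm, "nm/slice axial")
  cat("\n")
  invisible(x)
}

#' Convert a physical distance to a whole number of pixels
#'
#' Rounds to the nearest integer pixel count with ties rounded away from
#' zero (so 3.5 px becomes 4 px). The companion [px_to_nm()] converts exact
#' pixel counts back to nm, and `nm_to_px(px_to_nm(k)) == k` for all
#' integer `k >= 0`.
#'
#' @param d Distance in nm, `>= 0`.
#' @param cal A [pixel_calibration()].
#' @return Integer pixel count.
#' @export
nm_to_px <- function(d, cal) {
  stopifnot(inherits(cal, "pixel_calibration"))
  stopifnot(is.numeric(d), all(d >= 0))
  x <- d / cal$lateral_nm
  as.integer(floor(x + 0.5))  # ties away from zero (d >= 0)
}

#' @rdname nm_to_px
#' @param k Pixel count.
#' @export
px_to_nm <- function(k, cal) {
  stopifnot(inherits(cal, "pixel_calibration"))
  k * cal$lateral_nm
}
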
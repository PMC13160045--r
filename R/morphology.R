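# Shared raster helpers: Euclidean disc structuring elements, binary and
# grayscale morphology, component labeling, distance maps, gaussian blur.

# Offsets (dy, dx) of the discrete Euclidean disc {d: |d| <= r}.
disc_offsets <- function(r) {
  ri <- floor(r)
  g <- expand.grid(dy = -ri:ri, dx = -ri:ri)
  g <- g[g$dy^2 + g$dx^2 <= r^2, , drop = FALSE]
  as.matrix(g)
}

# 0/1 kernel matrix of the same disc, for EBImage erode/dilate.
disc_kernel <- function(r) {
  ri <- floor(r)
  n <- 2L * ri + 1L
  d <- outer((-ri:ri)^2, (-ri:ri)^2, "+")
  matrix(as.numeric(d <= r^2), n, n)
}

binary_dilate <- function(mask, r) {
  if (r <= 0) return(mask)
  out <- EBImage::dilate(matrix(as.numeric(mask), nrow(mask)), disc_kernel(r))
  matrix(as.logical(out > 0), nrow(mask))
}

binary_erode <- function(mask, r) {
  if (r <= 0) return(mask)
  out <- EBImage::erode(matrix(as.numeric(mask), nrow(mask)), disc_kernel(r))
  matrix(as.logical(out > 0), nrow(mask))
}

# 8-connected component labeling (background = 0).
label_components <- function(mask) {
  cpp_label8(matrix(as.logical(mask), nrow(mask)))
}

# Euclidean distance map: per-pixel distance to the nearest background pixel.
distance_map <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask))
  if (!any(m == 0)) return(matrix(Inf, nrow(mask), ncol(mask)))
  d <- EBImage::distmap(m, metric = "euclidean")
  matrix(as.numeric(d), nrow(mask))
}

# Gaussian blur with replicated borders (no wrap-around).
gauss_blur2d <- function(img, sigma) {
  if (sigma <= 0) return(img)
  size <- 2L * ceiling(3 * sigma) + 1L
  # the kernel cannot exceed the image
  max_size <- 2L * ((min(dim(img)) - 1L) %/% 2L) + 1L
  size <- min(size, max_size)
  k <- EBImage::makeBrush(size, shape = "gaussian", sigma = sigma)
  out <- EBImage::filter2(img, k, boundary = "replicate")
  matrix(as.numeric(out), nrow(img))
}

# Normalized masked gaussian blur: smooths img within the mask without
# bleeding background values across the mask border (normalized
# convolution). Pixels outside the mask are returned as 0.
gauss_blur2d_masked <- function(img, sigma, mask) {
  if (sigma <= 0) return(img * mask)
  mm <- matrix(as.numeric(mask), nrow(mask))
  num <- gauss_blur2d(img * mm, sigma)
  den <- gauss_blur2d(mm, sigma)
  out <- matrix(0, nrow(img), ncol(img))
  inside <- mm > 0
  out[inside] <- num[inside] / den[inside]
  out
}

#' Rolling-ball background subtraction
#'
#' Estimates the background of a 2D image as the grayscale opening with a
#' flat Euclidean-disc ("ball") structuring element of the given radius and
#' subtracts it, clipping at zero. Features narrower than the ball are
#' preserved; any structure the ball can roll under (including a constant
#' offset) is removed. The neighborhood is clipped at the image border.
#'
#' @param image Numeric matrix.
#' @param radius Ball radius in pixels (`>= 1`, smaller than the image
#'   extent).
#' @return Background-subtracted matrix, everywhere `>= 0` and `<=` the
#'   input.
#' @export
rolling_ball_subtract <- function(image, radius) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (radius < 1) stop("rolling-ball radius must be >= 1")
  if (radius >= min(dim(image))) {
    stop("rolling-ball radius (", radius, ") must be smaller than the ",
         "image extent (", min(dim(image)), ")")
  }
  r <- as.integer(floor(radius))
  bg <- cpp_disc_dilate(cpp_disc_erode(image, r), r)
  pmax(image - bg, 0)
}
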
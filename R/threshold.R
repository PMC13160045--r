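#' Automatic intensity thresholds
#'
#' All methods operate on a 256-bin histogram spanning the observed
#' `[min, max]` intensity range and return a threshold *value* located on a
#' bin edge; foreground is `intensity >= threshold`.
#'
#' * `"otsu"` maximizes the between-class variance over all 255 cut
#'   positions (first maximum on ties).
#' * `"isodata"` iterates the Ridler-Calvard rule (threshold = mean of the
#'   two class means) to a fixed point.
#' * `"li"` iterates Li's minimum-cross-entropy update to a fixed point.
#' * `"triangle"` takes the bin maximizing the distance between the
#'   histogram and the chord from the histogram peak to its far tail end.
#'
#' @param x Numeric vector, matrix or array of intensities.
#' @param method Threshold method.
#' @return A single numeric threshold.
#' @examples
#' img <- c(rnorm(500, 10, 1), rnorm(500, 60, 2))
#' auto_threshold(img, "otsu")
#' @export
auto_threshold <- function(x, method = c("otsu", "li", "triangle",
                                         "isodata")) {
  method <- match.arg(method)
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  if (!length(v)) stop("no finite intensities")
  lo <- min(v)
  hi <- max(v)
  if (lo == hi) stop("cannot threshold a constant image")
  nb <- 256L
  width <- (hi - lo) / nb
  bin <- pmin(pmax(floor((v - lo) / width), 0), nb - 1L)  # 0-based bin index
  counts <- tabulate(bin + 1L, nbins = nb)
  centers <- lo + (seq_len(nb) - 0.5) * width
  k <- switch(method,
    otsu = thr_otsu(counts, centers),
    isodata = thr_isodata(counts, centers),
    li = thr_li(counts, centers),
    triangle = thr_triangle(counts)
  )
  # cut after bin k (1-based): threshold on the edge between bins k and k+1
  lo + k * width
}

thr_otsu <- function(counts, centers) {
  n <- sum(counts)
  w0 <- cumsum(counts)[-length(counts)]
  w1 <- n - w0
  s0 <- cumsum(counts * centers)[-length(counts)]
  stot <- sum(counts * centers)
  m0 <- ifelse(w0 > 0, s0 / w0, 0)
  m1 <- ifelse(w1 > 0, (stot - s0) / w1, 0)
  bcv <- w0 * w1 * (m0 - m1)^2
  bcv[w0 == 0 | w1 == 0] <- -Inf
  which.max(bcv)
}

thr_isodata <- function(counts, centers) {
  t_val <- sum(counts * centers) / sum(counts)
  for (i in 1:200) {
    lowi <- centers < t_val
    if (!any(counts[lowi]) || !any(counts[!lowi])) break
    m0 <- sum(counts[lowi] * centers[lowi]) / sum(counts[lowi])
    m1 <- sum(counts[!lowi] * centers[!lowi]) / sum(counts[!lowi])
    t_new <- (m0 + m1) / 2
    if (abs(t_new - t_val) < 1e-9 * abs(diff(range(centers)))) {
      t_val <- t_new
      break
    }
    t_val <- t_new
  }
  max(1L, min(255L, as.integer(round((t_val - centers[1]) /
                                       diff(centers[1:2]) + 0.5))))
}

thr_li <- function(counts, centers) {
  # shift to a strictly positive scale (cross entropy needs positive means)
  eps <- diff(range(centers)) * 1e-3
  cpos <- centers - centers[1] + eps
  t_val <- sum(counts * cpos) / sum(counts)
  for (i in 1:200) {
    lowi <- cpos <= t_val
    if (!any(counts[lowi]) || !any(counts[!lowi])) break
    m0 <- sum(counts[lowi] * cpos[lowi]) / sum(counts[lowi])
    m1 <- sum(counts[!lowi] * cpos[!lowi]) / sum(counts[!lowi])
    t_new <- (m0 - m1) / (log(m0) - log(m1))
    if (!is.finite(t_new) || abs(t_new - t_val) < 1e-9 * max(cpos)) {
      if (is.finite(t_new)) t_val <- t_new
      break
    }
    t_val <- t_new
  }
  max(1L, min(255L, as.integer(round((t_val - cpos[1]) /
                                       diff(centers[1:2]) + 0.5))))
}

thr_triangle <- function(counts) {
  peak <- which.max(counts)
  nz <- which(counts > 0)
  # chord toward the longer tail
  far <- if ((max(nz) - peak) >= (peak - min(nz))) max(nz) else min(nz)
  if (far == peak) return(max(1L, min(255L, peak)))
  idx <- seq(min(peak, far), max(peak, far))
  # distance from histogram to the peak-far chord
  x1 <- peak; y1 <- counts[peak]; x2 <- far; y2 <- counts[far]
  d <- abs((y2 - y1) * idx - (x2 - x1) * counts[idx] + x2 * y1 - y2 * x1)
  max(1L, min(255L, idx[which.max(d)]))
}

#' Otsu threshold of a 2D image
#'
#' Between-class-variance maximization over a 256-bin histogram spanning the
#' observed range; used to derive the confocal presynaptic mask from the
#' vesicle-marker channel.
#'
#' @param image Numeric matrix with at least two distinct values.
#' @return Threshold value; foreground is `image >= threshold`.
#' @export
otsu_threshold <- function(image) {
  auto_threshold(image, "otsu")
}
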
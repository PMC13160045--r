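# Independent brute-force oracles and small scene builders shared by the
# test files. Oracles are deliberately naive (direct enumeration) and do not
# share code paths with the implementation they check.

# Exhaustive Otsu: split a 256-bin histogram at every cut and compute the
# between-class variance directly from the binned values.
bf_otsu <- function(v) {
  v <- as.numeric(v)
  lo <- min(v); hi <- max(v)
  nb <- 256L
  width <- (hi - lo) / nb
  bin <- pmin(pmax(floor((v - lo) / width), 0), nb - 1L)
  centers <- lo + (bin + 0.5) * width
  best <- -Inf; best_k <- 1L
  for (k in 1:(nb - 1L)) {
    low <- centers[bin < k]
    high <- centers[bin >= k]
    if (!length(low) || !length(high)) next
    w0 <- length(low) / length(v)
    w1 <- 1 - w0
    bcv <- w0 * w1 * (mean(low) - mean(high))^2
    if (bcv > best) { best <- bcv; best_k <- k }
  }
  lo + best_k * width
}

# Brute-force flat grayscale erosion/dilation with a Euclidean disc,
# neighborhood clipped at the image border.
bf_disc_morph <- function(img, r, fun) {
  ri <- floor(r)
  off <- expand.grid(dy = -ri:ri, dx = -ri:ri)
  off <- off[off$dy^2 + off$dx^2 <= r^2, ]
  nr <- nrow(img); nc <- ncol(img)
  out <- img
  for (x in seq_len(nc)) for (y in seq_len(nr)) {
    yy <- y + off$dy; xx <- x + off$dx
    k <- yy >= 1 & yy <= nr & xx >= 1 & xx <= nc
    out[y, x] <- fun(img[cbind(yy[k], xx[k])])
  }
  out
}

bf_rolling_ball <- function(img, r) {
  bg <- bf_disc_morph(bf_disc_morph(img, r, min), r, max)
  pmax(img - bg, 0)
}

# Brute-force seeded region growing: repeatedly scan all (unlabeled pixel,
# adjacent label) frontier pairs and commit the minimum under the ordering
# (intensity, label, column-major raster index). 8-connected.
bf_srg <- function(img, seeds, mask) {
  nr <- nrow(img); nc <- ncol(img)
  lab <- seeds * (seeds > 0) * mask
  nbrs <- function(y, x) {
    g <- expand.grid(dy = -1:1, dx = -1:1)
    g <- g[!(g$dy == 0 & g$dx == 0), ]
    yy <- y + g$dy; xx <- x + g$dx
    k <- yy >= 1 & yy <= nr & xx >= 1 & xx <= nc
    cbind(yy[k], xx[k])
  }
  repeat {
    cand <- NULL
    for (x in seq_len(nc)) for (y in seq_len(nr)) {
      if (!mask[y, x] || lab[y, x] != 0) next
      nb <- nbrs(y, x)
      ls <- lab[nb]
      ls <- ls[ls > 0]
      if (!length(ls)) next
      for (l in unique(ls)) {
        cand <- rbind(cand, c(img[y, x], l, (x - 1) * nr + y))
      }
    }
    if (is.null(cand)) break
    o <- order(cand[, 1], cand[, 2], cand[, 3])
    pick <- cand[o[1], ]
    idx <- pick[3]
    lab[((idx - 1) %% nr) + 1, ((idx - 1) %/% nr) + 1] <- pick[2]
  }
  lab
}

# Exact minimum-cost assignment by bitmask dynamic programming (small n),
# used to match recovered units to ground-truth units by centroid distance.
bf_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n, n <= 12)
  full <- bitwShiftL(1L, n) - 1L
  dp <- rep(Inf, full + 1L)
  choice <- matrix(NA_integer_, full + 1L, n)
  dp[1] <- 0
  for (m in 0:(full - 1L)) {
    if (!is.finite(dp[m + 1L])) next
    i <- sum(bitwAnd(m, bitwShiftL(1L, 0:(n - 1L))) > 0) + 1L  # next row
    for (j in 0:(n - 1L)) {
      if (bitwAnd(m, bitwShiftL(1L, j)) > 0) next
      m2 <- bitwOr(m, bitwShiftL(1L, j))
      v <- dp[m + 1L] + cost[i, j + 1L]
      if (v < dp[m2 + 1L]) {
        dp[m2 + 1L] <- v
        choice[m2 + 1L, ] <- choice[m + 1L, ]
        choice[m2 + 1L, i] <- j + 1L
      }
    }
  }
  choice[full + 1L, ]
}

# Labels of `rl` matched to labels of `tl` (equal label counts) by centroid
# distance (exact assignment; small n only).
match_units <- function(tl, rl) {
  cen <- function(lab) {
    t(vapply(seq_len(max(lab)), function(id) {
      colMeans(which(lab == id, arr.ind = TRUE))
    }, numeric(2)))
  }
  ct <- cen(tl); cr <- cen(rl)
  cost <- outer(seq_len(nrow(ct)), seq_len(nrow(cr)),
                Vectorize(function(i, j) sqrt(sum((ct[i, ] - cr[j, ])^2))))
  bf_assignment(cost)
}

# Overlap-based matching for larger label sets: each true unit is matched
# to the recovered label with maximal pixel overlap; asserts a bijection.
match_units_overlap <- function(tl, rl) {
  tab <- table(factor(tl[tl > 0], levels = seq_len(max(tl))),
               factor(rl[tl > 0], levels = seq_len(max(rl))))
  m <- apply(tab, 1, which.max)
  stopifnot(!anyDuplicated(m))
  as.integer(m)
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# Gaussian protein trace on the standard 750 nm / 22.7 nm profile lattice.
sim_profile <- function(center_nm, amp = 100, sd_nm = 45,
                        marker_sd = 45, spacing = 22.7, half_nm = 375) {
  pos <- seq(-floor(half_nm / spacing), floor(half_nm / spacing)) * spacing
  line_profile(pos, list(
    az_marker = 150 * exp(-pos^2 / (2 * marker_sd^2)),
    protein_of_interest = amp * exp(-(pos - center_nm)^2 / (2 * sd_nm^2))
  ))
}
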
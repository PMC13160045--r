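cfg <- experiment_config()
cal <- pixel_calibration(22.7)

test_that("inclusion-mask dilation matches the per-pixel distance oracle", {
  img <- matrix(0, 21, 21)
  img[11, 11] <- 10
  mask <- build_inclusion_mask(img, 5, cfg)  # dilation radius 6
  # oracle: every pixel within Euclidean distance 6 of the seed pixel
  d <- sqrt(outer((1:21 - 11)^2, (1:21 - 11)^2, "+"))
  expect_identical(mask$pixels, d <= 6)
  expect_equal(sum(mask$pixels), 113L)  # discrete Euclidean disc, r = 6
  # dilation 0 returns the thresholded input unchanged
  m0 <- build_inclusion_mask(img, 5, experiment_config(enface_dilation_px = 0L))
  expect_identical(m0$pixels, img >= 5)
  expect_error(build_inclusion_mask(img, 50, cfg), "empty mask")
})

test_that("the 6-pixel dilation at 22.7 nm/px is a 136 nm margin", {
  expect_identical(trunc(px_to_nm(cfg$enface_dilation_px, cal)), 136)
})

test_that("cluster detection respects the inclusion mask and the definitions", {
  img <- matrix(0, 40, 40)
  paint <- function(img, cx, cy, r, val) {
    d <- sqrt(outer((1:40 - cy)^2, (1:40 - cx)^2, "+"))
    img[d <= r] <- val
    img
  }
  img <- paint(img, 10, 10, 2, 50)
  img <- paint(img, 20, 12, 2, 80)
  img <- paint(img, 12, 25, 2, 60)
  img <- paint(img, 36, 36, 2, 90)   # outside the inclusion region
  inc <- mask_image(matrix(sqrt(outer((1:40 - 15)^2, (1:40 - 15)^2, "+")) <= 15,
                           40, 40), list(method = "manual"))
  cl <- detect_clusters(img, 30, inc, az_center = c(15, 15) * 22.7, cal, cfg)
  expect_equal(nrow(cl), 3L)
  expect_equal(cl$integrated_intensity, cl$area_px * cl$mean_intensity)
  # definition arithmetic: area 10, mean 50 -> integrated 500
  img2 <- matrix(0, 20, 20); img2[5, 1:10] <- 50
  inc2 <- mask_image(matrix(TRUE, 20, 20), list(method = "all"))
  cl2 <- detect_clusters(img2, 10, inc2, c(0, 0), cal, cfg)
  expect_equal(cl2$area_px, 10L)
  expect_equal(cl2$integrated_intensity, 500)
})

test_that("the optional distance band keeps only in-band clusters", {
  img <- matrix(0, 40, 40)
  img[20, 22] <- 100   # ~2.2 px from center -> ~50 nm
  img[20, 31] <- 100   # ~11 px -> ~250 nm
  inc <- mask_image(matrix(TRUE, 40, 40), list(method = "all"))
  ctr <- c((20 - 1 + 0.5) * 22.7, (20 - 1 + 0.5) * 22.7)  # (x, y) nm
  all_cl <- detect_clusters(img, 50, inc, ctr, cal, cfg)
  expect_equal(nrow(all_cl), 2L)
  banded <- detect_clusters(img, 50, inc, ctr, cal,
                            experiment_config(distance_band_nm = c(100, 300)))
  expect_equal(nrow(banded), 1L)
  expect_gt(banded$distance_nm, 100)
})

test_that("summaries follow the definitions, including the empty case", {
  empty <- detect_clusters(matrix(0, 5, 5), 1,
                           mask_image(matrix(TRUE, 5, 5), list(method = "m")),
                           c(0, 0), cal, cfg)
  s0 <- enface_summary(empty)
  expect_equal(s0$n_objects, 0L)
  expect_true(is.na(s0$mean_distance_nm))
  two <- data.frame(distance_nm = c(200, 300),
                    integrated_intensity = c(10, 30))
  s2 <- enface_summary(two)
  expect_equal(s2$mean_distance_nm, 250)
  expect_equal(s2$mean_integrated_intensity, 20)
  expect_equal(s2$total_integrated_intensity, 40)
})

test_that("raising the threshold never increases the count of resolved objects", {
  g <- generate_sted_field(synth_sted_params(n_sideview = 0, n_enface = 4,
                                             poisson_scale = 0,
                                             read_noise_sd = 0, seed = 23))
  prot <- get_channel(g$field, "protein_of_interest")
  inc <- mask_image(matrix(TRUE, nrow(prot), ncol(prot)), list(method = "m"))
  # above the level at which neighboring clusters merge, counts are
  # monotone non-increasing in the threshold
  counts <- vapply(seq(20, 120, by = 5), function(thr) {
    nrow(detect_clusters(prot, thr, inc, c(0, 0), cal, cfg))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("integrated intensity ignores relabeling and mask dilation", {
  g <- generate_sted_field(synth_sted_params(n_sideview = 0, n_enface = 1,
                                             poisson_scale = 0,
                                             read_noise_sd = 0, seed = 29))
  ves <- get_channel(g$field, "vesicle_marker")
  prot <- get_channel(g$field, "protein_of_interest")
  ctr <- az_center_nm(get_channel(g$field, "az_marker"), 50, cal)
  a <- detect_clusters(prot, 30, build_inclusion_mask(ves, 20, cfg), ctr, cal,
                       cfg)
  b <- detect_clusters(prot, 30,
                       build_inclusion_mask(ves, 20,
                         experiment_config(enface_dilation_px = 9L)),
                       ctr, cal, cfg)
  expect_equal(sort(a$integrated_intensity), sort(b$integrated_intensity))
})

test_that("noise-free scenes recover counts and distances exactly", {
  p <- synth_sted_params(n_sideview = 0, n_enface = 6,
                         clusters_per_synapse = 5L,
                         poisson_scale = 0, read_noise_sd = 0, seed = 37)
  g <- generate_sted_field(p)
  ves <- get_channel(g$field, "vesicle_marker")
  prot <- get_channel(g$field, "protein_of_interest")
  mk <- get_channel(g$field, "az_marker")
  inc <- build_inclusion_mask(ves, 25, cfg)
  for (s in Filter(function(x) x$type == "enface", g$truth$synapses)) {
    azc <- az_center_nm(mk, 50, cal, near_px = s$center_px)
    cl <- detect_clusters(prot, 30, inc, azc, cal, cfg)
    ctr <- (s$center_px + 0.5) * 22.7
    mine <- cl[sqrt((cl$centroid_x_nm - ctr["x"])^2 +
                      (cl$centroid_y_nm - ctr["y"])^2) < 500, ]
    expect_equal(nrow(mine), 5L)
    expect_true(all(abs(mine$distance_nm - s$cluster_radii_nm[1]) <= 22.7))
  }
})

test_that("counts recover in at least 90% of noisy synapses at SNR 10", {
  p <- synth_sted_params(n_sideview = 0, n_enface = 50, seed = 41)
  g <- generate_sted_field(p)
  ves <- get_channel(g$field, "vesicle_marker")
  prot <- get_channel(g$field, "protein_of_interest")
  mk <- get_channel(g$field, "az_marker")
  inc <- build_inclusion_mask(ves, 30, cfg)
  hits <- vapply(Filter(function(x) x$type == "enface", g$truth$synapses),
                 function(s) {
    azc <- az_center_nm(mk, 60, cal, near_px = s$center_px)
    cl <- detect_clusters(prot, 45, inc, azc, cal, cfg)
    ctr <- (s$center_px + 0.5) * 22.7
    mine <- cl[sqrt((cl$centroid_x_nm - ctr["x"])^2 +
                      (cl$centroid_y_nm - ctr["y"])^2) < 500, ]
    nrow(mine) == 4L
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
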
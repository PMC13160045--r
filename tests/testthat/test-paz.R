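cfg <- experiment_config()

test_that("upper-half projections use the documented slice rule", {
  mk_vol <- function(nz, hot) {
    arr <- array(0, c(6, 6, nz))
    for (z in seq_len(nz)) arr[2, 2, z] <- hot[z]
    image_volume(list(brp = arr), pixel_calibration(50, 200))
  }
  # Z = 4: slices 1-2 are the upper half (0-based {0, 1})
  v <- mk_vol(4, c(5, 9, 50, 1))
  pr <- upper_half_projection(v, cfg)
  expect_equal(pr$channels$brp[2, 2], 9)   # slice 3 value 50 excluded
  # Z = 5 (odd): middle slice included -> slices {0, 1, 2}
  v5 <- mk_vol(5, c(1, 2, 30, 90, 4))
  expect_equal(upper_half_projection(v5, cfg)$channels$brp[2, 2], 30)
  # the "last" flag flips which half is projected
  pr_last <- upper_half_projection(v, experiment_config(upper_half = "last"))
  expect_equal(pr_last$channels$brp[2, 2], 50)
})

test_that("the total 2D mask thresholds the plain channel sum", {
  a <- matrix(c(rep(2, 60), rep(50, 40)), 10, 10)
  b <- matrix(c(rep(3, 60), rep(70, 40)), 10, 10)
  f <- image_field(list(nwk = a, dyn = b), pixel_calibration(50))
  m <- total_mask_2d(f, cfg)
  expect_identical(m$pixels, (a + b) >= m$provenance$threshold)
  expect_identical(m$pixels, a + b > 100)
  f0 <- image_field(list(nwk = matrix(1, 5, 5)), pixel_calibration(50))
  expect_error(total_mask_2d(f0, cfg), "constant")
})

test_that("composite recipes combine mean-normalized channels with clamping", {
  nwk <- matrix(4, 6, 6); dyn <- matrix(10, 6, 6); brp <- matrix(0, 6, 6)
  brp[3, 3] <- 36  # mean 1
  f <- image_field(list(nwk = nwk, dyn = dyn, brp = brp),
                   pixel_calibration(50))
  comp <- paz_composite(f, composite_recipe(c("nwk", "dyn")))
  expect_equal(comp, matrix(2, 6, 6))
  full <- paz_composite(f, composite_recipe_preset("default"))
  expect_equal(full[3, 3], 0)          # clamped where brp dominates
  expect_equal(full[1, 1], 2)
  unclamped <- paz_composite(f, composite_recipe(c("nwk", "dyn"), "brp",
                                                 clamp = FALSE))
  expect_equal(unclamped[3, 3], 2 - 36)
  f2 <- image_field(list(nwk = matrix(0, 6, 6)), pixel_calibration(50))
  expect_error(paz_composite(f2, composite_recipe("nwk")), "zero mean")
})

test_that("seeded region growing matches the brute-force oracle", {
  set.seed(31)
  relabel <- function(lab) as.integer(factor(lab, levels = unique(lab[lab > 0])))
  for (i in 1:6) {
    n <- sample(8:16, 1)
    img <- matrix(round(runif(n * n) * 20), n, n)
    mask <- matrix(runif(n * n) < 0.9, n, n)
    seeds <- matrix(0L, n, n)
    k <- sample(2:4, 1)
    pos <- which(mask)[sample(sum(mask), k)]
    seeds[pos] <- seq_len(k)
    got <- perizone:::cpp_srg(img, seeds, mask)
    want <- bf_srg(img, seeds, mask)
    expect_identical(got, matrix(as.integer(want), n, n))
  }
})

test_that("two basins split along the bright ridge between them", {
  img <- matrix(1, 12, 16)
  img[, 8:9] <- 10  # ridge columns
  img[6, 3] <- 0; img[6, 14] <- 0
  mask <- matrix(TRUE, 12, 16)
  seg <- segment_paz_units(img, mask_image(mask, list(method = "m")), cfg)
  expect_equal(seg$n_units, 2L)
  left <- seg$labels[, 1:7]; right <- seg$labels[, 10:16]
  expect_equal(length(unique(as.vector(left))), 1L)
  expect_equal(length(unique(as.vector(right))), 1L)
  expect_false(unique(as.vector(left)) == unique(as.vector(right)))
  # every mask pixel is labeled: units partition the mask
  expect_true(all(seg$labels[mask] > 0))
  flat <- matrix(5, 12, 16)
  expect_error(segment_paz_units(flat, mask_image(mask, list(method = "m")),
                                 cfg), "flat")
})

test_that("a noise-free K = 9 scene yields 9 units with Jaccard >= 0.8", {
  g <- generate_nmj_volume(synth_nmj_params(size = c(160L, 160L, 6L),
                                            bouton_radius_px = 58,
                                            n_units = 9L, mesh_enrichment = 2,
                                            brp_fraction = 0,
                                            poisson_scale = 0,
                                            read_noise_sd = 0, seed = 19))
  res <- analyze_nmj_paz(g$volume, cfg)
  expect_equal(res$segmentation$n_units, 9L)
  tl <- g$truth$labels
  rl <- res$segmentation$labels
  match <- match_units(tl, rl)  # Hungarian on centroid distance
  for (id in 1:9) {
    expect_gte(jaccard(tl == id, rl == match[id]), 0.8)
  }
})

test_that("Euclidean distance maps match an all-pairs oracle", {
  mask <- matrix(FALSE, 9, 9)
  mask[3:7, 3:7] <- TRUE  # 5x5 square
  edm <- perizone:::distance_map(mask)
  bg <- which(!mask, arr.ind = TRUE)
  for (p in which(mask)) {
    rc <- arrayInd(p, dim(mask))
    d <- min(sqrt((bg[, 1] - rc[1])^2 + (bg[, 2] - rc[2])^2))
    expect_equal(edm[p], d, tolerance = 1e-6)
  }
})

test_that("edge exclusion applies the mean-EDM cutoff", {
  mask <- matrix(FALSE, 30, 40)
  mask[2:29, 2:39] <- TRUE
  labels <- matrix(0L, 30, 40)
  labels[2:29, 2:5] <- 1L     # hugs the border: low mean EDM
  labels[10:20, 15:30] <- 2L  # deep interior
  pu <- paz_units(labels, mask)
  pu <- exclude_edge_units(pu, cfg)
  expect_true(pu$units[[1]]$edge_excluded)
  expect_lt(pu$units[[1]]$mean_edm, 7.5)
  expect_false(pu$units[[2]]$edge_excluded)
  expect_gt(pu$units[[2]]$mean_edm, 7.5)
})

test_that("mesh/core splitting matches the distance-to-boundary oracle", {
  # 20x20 px unit at 25 nm/px with a 175 nm (7 px) mesh -> 6x6 core
  labels <- matrix(0L, 24, 24)
  labels[3:22, 3:22] <- 1L
  pu <- paz_units(labels, labels > 0)
  pu <- split_mesh_core(pu, pixel_calibration(25), cfg)
  core <- matrix(FALSE, 24, 24)
  core[10:15, 10:15] <- TRUE
  got_core <- matrix(FALSE, 24, 24); got_core[pu$units[[1]]$core_idx] <- TRUE
  expect_identical(got_core, core)
  # partition contract
  expect_setequal(c(pu$units[[1]]$mesh_idx, pu$units[[1]]$core_idx),
                  pu$units[[1]]$idx)
  expect_length(intersect(pu$units[[1]]$mesh_idx, pu$units[[1]]$core_idx), 0)
  # a unit narrower than twice the mesh width has no core
  thin <- matrix(0L, 20, 20); thin[5:14, 5:10] <- 1L
  put <- split_mesh_core(paz_units(thin, thin > 0), pixel_calibration(25), cfg)
  expect_true(put$units[[1]]$core_empty)
})

test_that("polarization follows the log-ratio closed form and antisymmetry", {
  labels <- matrix(0L, 24, 24); labels[3:22, 3:22] <- 1L
  pu <- split_mesh_core(paz_units(labels, labels > 0), pixel_calibration(25),
                        cfg)
  ch_eq <- matrix(5, 24, 24)
  expect_equal(polarization(ch_eq, pu, cfg), 0)
  mesh <- matrix(FALSE, 24, 24); mesh[pu$units[[1]]$mesh_idx] <- TRUE
  ch2 <- matrix(3, 24, 24); ch2[mesh] <- 6
  expect_equal(polarization(ch2, pu, cfg), 1)  # mesh = 2x core, base 2
  swapped <- matrix(6, 24, 24); swapped[mesh] <- 3
  expect_identical(polarization(ch2, pu, cfg),
                   -polarization(swapped, pu, cfg))  # exact antisymmetry
  zero <- matrix(0, 24, 24)
  expect_true(is.na(polarization(zero, pu, cfg)))
})

test_that("Brp object density follows the definition", {
  # 5 puncta in a 10 um^2 mask at 50 nm pixels (10 um^2 = 4000 px)
  mask <- matrix(FALSE, 80, 80); mask[1:50, 1:80] <- TRUE
  brp <- matrix(0, 80, 80)
  for (xy in list(c(10, 10), c(10, 40), c(30, 20), c(40, 60), c(20, 70))) {
    brp[xy[1], xy[2]] <- 500
  }
  f <- image_field(list(brp = brp), pixel_calibration(50))
  got <- brp_objects_and_density(f, mask_image(mask, list(method = "m")),
                                 pixel_calibration(50),
                                 experiment_config(channel_thresholds =
                                                     c(brp = 100)))
  expect_equal(nrow(got$objects), 5L)
  expect_equal(got$density_per_um2, 0.5)
  expect_equal(got$objects$integrated_intensity,
               got$objects$area_px * got$objects$mean_intensity)
})

test_that("noise-free scenes recover every placed Brp punctum", {
  g <- generate_nmj_volume(synth_nmj_params(brp_fraction = 0.6,
                                            poisson_scale = 0,
                                            read_noise_sd = 0, seed = 23))
  f <- upper_half_projection(g$volume, cfg)
  mask <- mask_image(g$truth$footprint, list(method = "truth"))
  got <- brp_objects_and_density(f, mask, f$calibration, cfg,
                                 labels = g$truth$labels)
  truth_centers <- do.call(rbind, lapply(
    Filter(function(u) u$brp_positive, g$truth$units),
    function(u) u$brp_center_px))
  expect_equal(nrow(got$objects), nrow(truth_centers))  # 12 of K = 20
  for (i in seq_len(nrow(truth_centers))) {
    d <- sqrt((got$objects$centroid_x_nm / 50 - 0.5 - truth_centers[i, "x"])^2 +
              (got$objects$centroid_y_nm / 50 - 0.5 - truth_centers[i, "y"])^2)
    expect_lte(min(d), 1)
  }
  # density against the arithmetic definition on the same mask
  expect_equal(got$density_per_um2,
               nrow(got$objects) / (sum(g$truth$footprint) * 50^2 / 1e6))
  # p = 0 scenes contain no objects at all
  g0 <- generate_nmj_volume(synth_nmj_params(brp_fraction = 0,
                                             poisson_scale = 0,
                                             read_noise_sd = 0, seed = 24))
  f0 <- upper_half_projection(g0$volume, cfg)
  got0 <- brp_objects_and_density(f0,
                                  mask_image(g0$truth$footprint,
                                             list(method = "truth")),
                                  f0$calibration, cfg)
  expect_equal(nrow(got0$objects), 0L)
  expect_equal(got0$density_per_um2, 0)
})

test_that("unit classification flags Brp content and Pak apposition", {
  labels <- matrix(0L, 20, 20)
  labels[2:10, 2:19] <- 1L
  labels[11:19, 2:19] <- 2L
  pu <- paz_units(labels, labels > 0)
  pu <- exclude_edge_units(pu, experiment_config(edm_edge_cutoff_px = 0.5))
  objs <- data.frame(unit_id = 1L)  # one punctum centroid in unit 1
  pak <- matrix(0, 20, 20); pak[labels > 0] <- 10  # Pak under every unit
  cls <- classify_units(pu, objs, pak,
                        experiment_config(channel_thresholds = c(pak = 5)))
  expect_true(cls$units$units[[1]]$brp_positive)
  expect_false(cls$units$units[[2]]$brp_positive)
  expect_equal(cls$pct_brp_positive, 50)
  expect_equal(cls$pct_pak_apposed, 100)
})

test_that("classification percentages are exact on noise-free K = 20 scenes", {
  g <- generate_nmj_volume(synth_nmj_params(brp_fraction = 0.6,
                                            poisson_scale = 0,
                                            read_noise_sd = 0, seed = 29))
  res <- analyze_nmj_paz(g$volume, cfg)
  expect_equal(res$segmentation$n_units, 20L)
  # match recovered to true units and compare flags one by one
  match <- match_units_overlap(g$truth$labels, res$segmentation$labels)
  truth_flags <- vapply(g$truth$units, function(u) u$brp_positive, logical(1))
  rec_units <- res$units$units
  for (id in seq_len(20)) {
    expect_identical(rec_units[[match[id]]]$brp_positive, truth_flags[id])
  }
  analyzed <- !vapply(rec_units, function(u) u$edge_excluded, logical(1))
  truth_for_rec <- logical(20)
  truth_for_rec[match] <- truth_flags
  expect_equal(res$summary$pct_brp_positive, 100 * mean(truth_for_rec[analyzed]))
  expect_equal(res$summary$pct_pak_apposed, 100)
})

test_that("polarization recovers the true enrichment on true unit polygons", {
  for (R in c(1, 2, 4)) {
    g <- generate_nmj_volume(synth_nmj_params(
      mesh_enrichment = c(nwk = R, dyn = 2, endoA = 2, dap160 = 2,
                          fasII = 2),
      brp_fraction = 0, poisson_scale = 0, read_noise_sd = 0, seed = 40 + R))
    f <- upper_half_projection(g$volume, cfg)
    pu <- paz_units(g$truth$labels, g$truth$footprint)
    pu <- exclude_edge_units(pu, cfg)
    pu <- split_mesh_core(pu, f$calibration, cfg)
    pol <- polarization(get_channel(f, "nwk"), pu, cfg)
    expect_equal(mean(pol, na.rm = TRUE), log2(R), tolerance = 0.05)
  }
})

test_that("mean recovered polarization increases strictly with enrichment", {
  rs <- c(1, 1.5, 2, 3, 4)
  reps <- 10
  means <- sapply(rs, function(R) {
    vals <- vapply(seq_len(reps), function(i) {
      g <- generate_nmj_volume(synth_nmj_params(
        size = c(96L, 96L, 4L), bouton_radius_px = 34, n_units = 8L,
        mesh_enrichment = c(nwk = R, dyn = 1.5, endoA = 1.5, dap160 = 1.5,
                            fasII = 1.5),
        brp_fraction = 0, seed = 100 * i + round(10 * R)))
      f <- upper_half_projection(g$volume, cfg)
      mask <- total_mask_2d(f, cfg)
      comp <- paz_composite(f, composite_recipe_preset("default"))
      seg <- segment_paz_units(comp, mask, cfg)
      pu <- paz_units(seg, mask)
      pu <- exclude_edge_units(pu, cfg)
      pu <- split_mesh_core(pu, f$calibration, cfg)
      mean(polarization(get_channel(f, "nwk"), pu, cfg), na.rm = TRUE)
    }, numeric(1))
    mean(vals)
  })
  expect_true(all(diff(means) > 0))
})

test_that("the fig9 composite dips at the true unit centers", {
  g <- generate_nmj_volume(synth_nmj_params(brp_fraction = 1,
                                            poisson_scale = 0,
                                            read_noise_sd = 0, seed = 31))
  f <- upper_half_projection(g$volume, cfg)
  comp <- paz_composite(f, composite_recipe_preset("fig9_fasII"))
  sm <- perizone:::snap_float32(perizone:::gauss_blur2d_masked(
    comp, 1, g$truth$footprint))
  for (u in g$truth$units[c(2, 9, 16)]) {
    cx <- round(u$centroid_px["x"]) + 1
    cy <- round(u$centroid_px["y"]) + 1
    win <- sm[(cy - 6):(cy + 6), (cx - 6):(cx + 6)]
    # the recorded center lies on the minimum plateau of the local dip
    # (the Brp+Pak subtraction clamps a neighborhood of the center to the
    # composite floor)
    expect_lte(win[7, 7], min(win) + 1e-9 * max(abs(comp)))
  }
})
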
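cfg <- experiment_config()

test_that("profiles of a constant field are constant at any angle", {
  cal <- pixel_calibration(22.7)
  m <- matrix(7, 64, 64)
  field <- image_field(list(az_marker = m, protein_of_interest = m), cal)
  for (ang in c(0, pi / 6, pi / 3, 2)) {
    roi <- sideview_roi(c(31.5, 31.5), ang, width_px = 9)
    pr <- extract_profile(field, roi, cfg)
    expect_equal(pr$intensities$protein_of_interest,
                 rep(7, length(pr$positions_nm)))
  }
})

test_that("the centered rolled average follows the box-filter definition", {
  v <- rep(0, 21); v[11] <- 1
  out <- perizone:::rolled_average(v, 5)
  expect_equal(out[9:13], rep(0.2, 5))
  expect_equal(sum(out != 0), 5L)
  # edges shrink to the valid window instead of padding
  w <- rep(1, 6)
  expect_equal(perizone:::rolled_average(w, 5), rep(1, 6))
  v2 <- c(10, rep(0, 9))
  expect_equal(perizone:::rolled_average(v2, 5)[1], 10 / 3)  # window {1,2,3}
})

test_that("an oblique protein band at +4 px lands at +4 samples", {
  # noise-free bar tilted so the profile axis is 30 degrees, protein offset
  # +90.8 nm = 4 px at the STED pixel pitch
  p <- synth_sted_params(n_sideview = 4, n_enface = 0, delta_nm = 90.8,
                         poisson_scale = 0, read_noise_sd = 0, seed = 21)
  g <- generate_sted_field(p)
  rois <- sideview_rois_from_truth(g$truth, cfg)
  for (i in 1:4) {
    roi <- rois[[i]]
    pr <- align_profile(extract_profile(g$field, roi, cfg))
    prot <- pr$intensities$protein_of_interest
    ref <- pr$intensities[[pr$reference_role]]
    expect_equal(which.max(prot) - which.max(ref), 4L)
  }
})

test_that("alignment and averaging is idempotent and scales to percent", {
  pr <- sim_profile(45)
  avg <- align_and_average(list(pr, pr), reference_mean = 1)
  aligned <- align_profile(pr)
  expect_equal(avg$intensities$protein_of_interest / 100,
               aligned$intensities$protein_of_interest)
  # {80, 120} with reference mean 100 -> {80%, 120%}
  two <- align_and_average(list(sim_profile(0, amp = 80),
                                sim_profile(0, amp = 120)),
                           reference_mean = 100)
  expect_equal(max(two$intensities$protein_of_interest), 100)  # mean of peaks
  one <- align_and_average(list(sim_profile(0, amp = 80)),
                           reference_mean = 100)
  expect_equal(max(one$intensities$protein_of_interest), 80)
})

test_that("positional jitter pulls the averaged peak below 100%", {
  set.seed(42)
  profiles <- lapply(runif(200, -68, 68), sim_profile)
  avg <- align_and_average(profiles, reference_mean = 100)
  expect_lt(max(avg$intensities$protein_of_interest), 100)
})

test_that("averaged-profile maximum decreases monotonically with jitter", {
  set.seed(7)
  maxima <- vapply(c(5, 20, 40, 68), function(j) {
    profiles <- lapply(runif(300, -j, j), sim_profile)
    max(align_and_average(profiles,
                          reference_mean = 100)$intensities$protein_of_interest)
  }, numeric(1))
  expect_true(all(diff(maxima) < 0))
})

test_that("window peaks enumerate only in-window samples", {
  pos <- seq(-16, 16) * 22.7
  prot <- rep(1, 33)
  prot[pos == -45.4] <- 7
  prot[pos == 90.8] <- 9
  mk <- exp(-pos^2 / 2000)
  pr <- align_profile(line_profile(pos, list(az_marker = mk,
                                             protein_of_interest = prot)))
  sym <- profile_metrics(pr, experiment_config(window_mode = "symmetric_68"))
  expect_equal(sym$window_peak, 7)  # the +90.8 peak is outside +/-68 nm
  expect_equal(sym$peak_to_peak_nm, 90.8)  # global argmax is still +90.8
  # coincident peaks give zero distance
  pr0 <- align_profile(line_profile(pos, list(az_marker = mk,
                                              protein_of_interest = mk)))
  expect_equal(profile_metrics(pr0, cfg)$peak_to_peak_nm, 0)
  # one-sided window ignores a dominant postsynaptic peak
  prot2 <- rep(1, 33)
  prot2[pos == -90.8] <- 50   # postsynaptic side (presynaptic_sign = +1)
  prot2[pos == 45.4] <- 3
  pr2 <- align_profile(line_profile(pos, list(az_marker = mk,
                                              protein_of_interest = prot2)))
  one <- profile_metrics(pr2, experiment_config(window_mode = "onesided_136"))
  expect_equal(one$window_peak, 3)
  # window past the profile end errors
  short <- align_profile(line_profile(pos[15:19],
                                      list(az_marker = mk[15:19],
                                           protein_of_interest = prot[15:19])))
  expect_error(profile_metrics(short, cfg), "window extends")
})

test_that("metrics are scale invariant in the expected way", {
  p <- synth_sted_params(n_sideview = 1, n_enface = 0, delta_nm = -45.4,
                         poisson_scale = 0, read_noise_sd = 0, seed = 31)
  g <- generate_sted_field(p)
  roi <- sideview_rois_from_truth(g$truth, cfg)[[1]]
  pr1 <- align_profile(extract_profile(g$field, roi, cfg))
  scaled <- g$field
  scaled$channels <- lapply(scaled$channels, function(ch) ch * 3.7)
  pr2 <- align_profile(extract_profile(scaled, roi, cfg))
  m1 <- profile_metrics(pr1, cfg)
  m2 <- profile_metrics(pr2, cfg)
  expect_equal(m2$peak_to_peak_nm, m1$peak_to_peak_nm)
  expect_equal(m2$window_peak, 3.7 * m1$window_peak)
})

test_that("the geometric screen accepts bars with clouds and rejects others", {
  p <- synth_sted_params(n_sideview = 1, n_enface = 0,
                         poisson_scale = 0, read_noise_sd = 0, seed = 8)
  g <- generate_sted_field(p)
  roi <- sideview_rois_from_truth(g$truth, cfg)[[1]]
  sc <- screen_sideview(g$field, roi, cfg)
  expect_true(sc$accept)
  expect_gte(sc$elongation, 2)
  expect_gte(sc$cloud_extent_nm, 250)
  # a 200 nm cloud is too narrow
  p2 <- synth_sted_params(n_sideview = 1, n_enface = 0, cloud_diam_nm = 200,
                          poisson_scale = 0, read_noise_sd = 0, seed = 8)
  g2 <- generate_sted_field(p2)
  sc2 <- screen_sideview(g2$field, sideview_rois_from_truth(g2$truth, cfg)[[1]],
                         cfg)
  expect_false(sc2$accept)
  expect_true(any(grepl("cloud < 250 nm", sc2$reasons)))
  # a circular marker is not bar-like
  p3 <- synth_sted_params(n_sideview = 1, n_enface = 0,
                          marker_length_nm = 80, marker_width_nm = 80,
                          poisson_scale = 0, read_noise_sd = 0, seed = 8)
  g3 <- generate_sted_field(p3)
  sc3 <- screen_sideview(g3$field, sideview_rois_from_truth(g3$truth, cfg)[[1]],
                         cfg)
  expect_false(sc3$accept)
  expect_true(any(grepl("not bar-like", sc3$reasons)))
})

test_that("offsets recover within one pixel on noise-free and noisy scenes", {
  deltas <- rep(c(-90.8, 0, 90.8), length.out = 24)
  p <- synth_sted_params(n_sideview = 24, n_enface = 0, delta_nm = deltas,
                         poisson_scale = 0, read_noise_sd = 0, seed = 17)
  g <- generate_sted_field(p)
  rois <- sideview_rois_from_truth(g$truth, cfg)
  err <- vapply(seq_along(rois), function(i) {
    pr <- align_profile(extract_profile(g$field, rois[[i]], cfg))
    profile_metrics(pr, cfg)$peak_to_peak_nm - deltas[i]
  }, numeric(1))
  expect_true(all(abs(err) <= 22.7 + 1e-9))
  # SNR >= 10 (Poisson scale 1 at peak amplitude 100)
  pn <- synth_sted_params(n_sideview = 24, n_enface = 0, delta_nm = deltas,
                          seed = 18)
  gn <- generate_sted_field(pn)
  roisn <- sideview_rois_from_truth(gn$truth, cfg)
  errn <- vapply(seq_along(roisn), function(i) {
    pr <- align_profile(extract_profile(gn$field, roisn[[i]], cfg))
    profile_metrics(pr, cfg)$peak_to_peak_nm - deltas[i]
  }, numeric(1))
  expect_gte(mean(abs(errn) <= 22.7 + 1e-9), 0.95)
})

test_that("alignment fails on a flat reference channel", {
  pos <- seq(-16, 16) * 22.7
  pr <- line_profile(pos, list(az_marker = rep(1, 33),
                               protein_of_interest = runif(33)))
  expect_error(align_profile(pr), "flat")
})
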
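test_that("pixel_dff normalizes per pixel against the pre-CSD baseline", {
  # constant movie -> all zeros; a pixel doubling its baseline -> 1.0
  arr <- array(100, c(20, 4, 4))
  arr[15, 2, 3] <- 200
  m <- csd_movie(arr, frame_rate_hz = 10, pixel_pitch_mm = 0.001)
  d <- pixel_dff(m, time_window(0, 1))
  expect_equal(d$data[1, 1, 1], 0)
  expect_equal(d$data[15, 2, 3], 1.0)
  # random fixture equals the per-pixel loop oracle
  set.seed(13)
  arr2 <- array(runif(10 * 3 * 3, 50, 150), c(10, 3, 3))
  m2 <- csd_movie(arr2, 10, 0.001)
  d2 <- pixel_dff(m2, time_window(0, 0.5))
  for (r in 1:3) for (cc in 1:3) {
    f0 <- mean(arr2[1:5, r, cc])
    expect_equal(d2$data[, r, cc], (arr2[, r, cc] - f0) / f0)
  }
  # non-positive baselines are masked and reported
  arr3 <- arr2; arr3[, 2, 2] <- -1
  expect_warning(d3 <- pixel_dff(csd_movie(arr3, 10, 0.001), time_window(0, 0.5)),
                 "masked")
  expect_true(all(is.na(d3$data[, 2, 2])))
})

test_that("soma ROI construction from a marker mask labels components by area", {
  mask <- matrix(0, 32, 32)
  mask[4:8, 4:8] <- 1        # 25 px
  mask[20:24, 20:24] <- 1    # 25 px
  mask[30, 30] <- 1          # 1 px, below min_px
  rs <- soma_rois_from_mask(mask, min_px = 5, max_px = 100)
  expect_length(rs$soma_rois, 2)
  expect_equal(rs$provenance, "mask-derived")
  expect_setequal(rs$soma_rois[[1]],
                  which(matrix(seq_len(32 * 32), 32, 32) %in%
                          outer(4:8, (4:8 - 1) * 32, "+")))
  # touching disks merge into one component
  mask2 <- matrix(0, 16, 16)
  mask2[4:6, 4:6] <- 1
  mask2[6:8, 6:8] <- 1
  rs2 <- soma_rois_from_mask(mask2, min_px = 3, max_px = 100, dilate_px = 0)
  expect_length(rs2$soma_rois, 1)
  # somata recovered 1:1 from the generator's planted mask
  s <- twophoton_scenario(grid = 48, duration_s = 30, n_somata = 8,
                          pre_csd_window = time_window(0, 10),
                          post_csd_window = time_window(15, 30), seed = 31)
  sim <- simulate_twophoton(s)
  rs3 <- soma_rois_from_mask(sim$mask > 0)
  expect_length(rs3$soma_rois, 8)
  planted <- lapply(sim$truth$soma_pixels, sort)
  recovered <- lapply(rs3$soma_rois, sort)
  expect_true(all(vapply(planted, function(p)
    any(vapply(recovered, identical, TRUE, y = p)), TRUE)))
})

test_that("roi_set enforces disjointness", {
  expect_error(roi_set(list(a = 1:5, b = 4:8), 20:30, "manual"), "disjoint")
  expect_error(roi_set(list(a = 1:5), 3:10, "manual"), "disjoint")
})

test_that("high-Ca mask equals a two-pass mean/SD oracle exactly", {
  set.seed(17)
  arr <- array(rnorm(200 * 5 * 5, 0, 0.1), c(200, 5, 5))
  arr[150, 2, 2] <- 5  # planted supra-threshold pixel-frame
  m <- csd_movie(arr, frame_rate_hz = 10, pixel_pitch_mm = 0.001)
  roi <- c(7, 12, 13)  # linear indices
  hm <- high_ca_mask(m, roi, k_sd = 4, ref = time_window(0, 10))
  mat <- matrix(arr, nrow = 200)
  for (j in seq_along(roi)) {
    px <- mat[, roi[j]]
    thr <- mean(px[1:100]) + 4 * sd(px[1:100])
    expect_identical(unname(hm[, j]), px > thr)
  }
  # planted event is flagged
  hm2 <- high_ca_mask(m, which(matrix(seq_len(25), 5, 5) == 7), 4, time_window(0, 10))
  expect_true(high_ca_mask(m, (2 - 1) + (2 - 1) * 5 + 1, 4, time_window(0, 10))[150, 1])
})

test_that("event probability counts pixel-frames: 2 hits in a 3-pixel,
           4-frame toy give 2/12", {
  arr <- array(0.0, c(14, 3, 1))
  set.seed(8)
  arr[1:10, , 1] <- rnorm(30, 0, 0.01)   # reference frames
  arr[12, 1, 1] <- 1                      # two supra-threshold pixel-frames
  arr[13, 3, 1] <- 1
  m <- csd_movie(arr, frame_rate_hz = 1, pixel_pitch_mm = 0.001)
  rois <- roi_set(list(s1 = 1:3), integer(0), "manual")
  ep <- event_probability(m, rois, eval_window = time_window(10, 14),
                          mode = "per_soma", ref = time_window(0, 10))
  expect_equal(ep$p_high, 2 / 12)
  expect_equal(ep$n_pixels, 3)
  expect_equal(ep$n_frames, 4)
})

test_that("p_high equals brute-force counting on random fixtures and stays
           in [0, 1]", {
  set.seed(23)
  for (k in 1:20) {
    nf <- sample(20:40, 1); npx <- sample(4:9, 1)
    arr <- array(rnorm(nf * npx, 0, 0.2), c(nf, npx, 1))
    m <- csd_movie(arr, 10, 0.001)
    nref <- nf %/% 2
    rois <- roi_set(list(s = seq_len(npx)), integer(0), "manual")
    ep <- suppressWarnings(
      event_probability(m, rois, time_window(nref / 10, nf / 10),
                        "per_soma", ref = time_window(0, nref / 10)))
    # brute force: per-pixel threshold from the reference, count by loops
    cnt <- 0L; used <- 0L
    for (p in seq_len(npx)) {
      px <- arr[, p, 1]
      mu <- mean(px[1:nref]); sdev <- sd(px[1:nref])
      if (sdev == 0) next
      used <- used + 1L
      for (f in (nref + 1):nf) if (px[f] > mu + 4 * sdev) cnt <- cnt + 1L
    }
    expect_equal(ep$n_high, cnt)
    expect_equal(ep$p_high, cnt / (used * (nf - nref)))
    expect_gte(ep$p_high, 0); expect_lte(ep$p_high, 1)
  }
})

test_that("noise-only exceedance sits at the Gaussian +4 SD tail", {
  s <- twophoton_scenario(grid = 32, duration_s = 90, n_somata = 0,
                          pre_csd_window = time_window(0, 30),
                          post_csd_window = time_window(30, 90),
                          soma_event_rate_hz = 0, gliopil_event_rate_hz = 0,
                          n_gliopil_patches = 0, seed = 55)
  sim <- simulate_twophoton(s)
  dff <- pixel_dff(sim$movie, time_window(0, 30))
  rois <- roi_set(list(), seq_len(32 * 32), "manual")
  ep <- event_probability(dff, rois, time_window(30, 90), "pooled_nonsoma",
                          ref = time_window(0, 30))
  p0 <- pnorm(-4)
  n <- ep$n_pixels * ep$n_frames
  mc_sd <- sqrt(p0 * (1 - p0) / n)
  # within 3 Monte-Carlo SDs plus the threshold-estimation bias allowance
  expect_lt(abs(ep$p_high - p0), 3 * mc_sd + 2.5e-3 / (30 * 30))
})

test_that("gliopil ROI selection recovers planted patches and falls back when
           empty", {
  s <- twophoton_scenario(grid = 40, duration_s = 120, n_somata = 4,
                          pre_csd_window = time_window(0, 60),
                          post_csd_window = time_window(70, 120),
                          n_gliopil_patches = 6, noise_sd_dff = 0.05, seed = 61)
  sim <- simulate_twophoton(s)
  dff <- pixel_dff(sim$movie, time_window(0, 60))
  nonsoma <- setdiff(seq_len(40 * 40), unlist(sim$truth$soma_pixels))
  ref <- time_window(0, 60)
  gl <- suppressWarnings(gliopil_roi_from_events(dff, list(ref), nonsoma))
  # every patch with >= 1 event inside the reference period is fully recovered
  ref_frames <- which(movie_times(dff) >= ref$start_s & movie_times(dff) < ref$end_s)
  for (g in seq_along(sim$truth$gliopil_patch_pixels)) {
    if (any(sim$truth$gliopil_event_idx[[g]] %in% ref_frames))
      expect_true(all(sim$truth$gliopil_patch_pixels[[g]] %in% gl))
  }
  # event-free movie falls back to the whole non-soma region with a warning
  s0 <- twophoton_scenario(grid = 24, duration_s = 40, n_somata = 2,
                           pre_csd_window = time_window(0, 20),
                           post_csd_window = time_window(20, 40),
                           soma_event_rate_hz = 0, gliopil_event_rate_hz = 0,
                           n_gliopil_patches = 0, noise_sd_dff = 1e-3, seed = 62)
  sim0 <- simulate_twophoton(s0)
  dff0 <- pixel_dff(sim0$movie, time_window(0, 20))
  ns0 <- setdiff(seq_len(24 * 24), unlist(sim0$truth$soma_pixels))
  # threshold at +30 SD so not a single noise pixel-frame can exceed it
  expect_warning(gl0 <- gliopil_roi_from_events(dff0, list(time_window(5, 20)),
                                                ns0, k_sd = 30),
                 "falling back")
  expect_true(attr(gl0, "fallback"))
  expect_equal(sort(gl0), sort(ns0))
})

test_that("correlation matrix properties: symmetry, unit diagonal, order
           invariance, degenerate pairs", {
  set.seed(41)
  tr <- matrix(rnorm(300 * 5), 300, 5)
  cm <- pairwise_soma_correlation(tr, "per_pair")
  expect_equal(cm, t(cm))
  expect_equal(unname(diag(cm)), rep(1, 5))
  m1 <- pairwise_soma_correlation(tr, "mean_per_recording")
  m2 <- pairwise_soma_correlation(tr[, 5:1], "mean_per_recording")
  expect_equal(m1, m2)
  # identical traces -> 1; negated -> -1
  expect_equal(pairwise_soma_correlation(cbind(tr[, 1], tr[, 1]),
                                         "mean_per_recording"), 1)
  expect_equal(pairwise_soma_correlation(cbind(tr[, 1], -tr[, 1]),
                                         "mean_per_recording"), -1)
  expect_warning(pairwise_soma_correlation(cbind(tr[, 1:2], 0), "per_pair"),
                 "zero-variance")
})
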
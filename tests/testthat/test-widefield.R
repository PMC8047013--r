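test_that("compute_dff uses the 40-s baseline ending 20 s before KCl", {
  # constant trace -> all-zero ΔF/F
  tr <- csd_trace(rep(5, 1200), rate_hz = 10, t0_s = -120, unit = "au")
  expect_true(all(compute_dff(tr, 0)$values == 0))
  # F0 during the baseline window, 3*F0 later -> ΔF/F = 2.0 (200%)
  v <- rep(100, 1200)
  v[1150] <- 300
  tr2 <- csd_trace(v, rate_hz = 10, t0_s = -120, unit = "au")
  expect_equal(compute_dff(tr2, 0)$values[1150], 2.0)
  # arbitrary fixture equals elementwise (x - mean_window) / mean_window
  set.seed(4)
  v3 <- runif(1200, 90, 110)
  tr3 <- csd_trace(v3, rate_hz = 10, t0_s = -120, unit = "au")
  d3 <- compute_dff(tr3, 0)
  tt <- trace_times(tr3)
  f0 <- mean(v3[tt >= -60 & tt < -20])
  expect_equal(d3$values, (v3 - f0) / f0)
  expect_equal(attr(d3, "baseline_f"), f0)
  # insufficient pre-KCl coverage is an error
  expect_error(compute_dff(csd_trace(rep(1, 100), 10, t0_s = -30), 0), "cover")
})

test_that("detection finds no events in pure noise and flags bad baselines", {
  set.seed(12)
  tr <- csd_trace(rnorm(6000, 0, 0.01), rate_hz = 10, t0_s = -120, unit = "dff")
  ev <- detect_csd_events(tr, time_window(-60, -20))
  expect_equal(nrow(ev), 0)
  const <- csd_trace(rep(0, 6000), rate_hz = 10, t0_s = -120, unit = "dff")
  expect_error(detect_csd_events(const, time_window(-60, -20)), "zero-variance")
})

test_that("onset of a noiseless ramp matches the closed-form crossing time", {
  # baseline ~ N(0, 0.01) only inside the stats window; ramp slope 0.05/s from t=0
  set.seed(3)
  rate <- 10
  t <- seq(-120, 200 - 0.1, by = 0.1)
  v <- numeric(length(t))
  v[t < 0] <- rnorm(sum(t < 0), 0, 0.01)
  v[t >= 0] <- 0.05 * t[t >= 0]
  tr <- csd_trace(v, rate_hz = rate, t0_s = -120, unit = "dff")
  bidx <- t >= -60 & t < -20
  thr <- mean(v[bidx]) + 5 * sd(v[bidx])
  # the ramp never subsides: passage is flagged undefined, onset still exact
  suppressWarnings(ev <- detect_csd_events(tr, time_window(-60, -20)))
  expect_equal(nrow(ev), 1)
  expect_true(is.na(ev$passage_s))
  expect_lt(abs(ev$onset_s - thr / 0.05), 1 / rate)
})

test_that("spline interpolation recovers an off-sample parabola vertex", {
  rate <- 10
  t <- seq(0, 20 - 0.1, by = 0.1)
  vertex_t <- 10.037; vertex_v <- 3
  v <- vertex_v - 0.1 * (t - vertex_t)^2
  tr <- csd_trace(v, rate_hz = rate, unit = "dff")
  pk <- peak_by_spline(tr, list(peak_s = t[which.max(v)]))
  expect_lt(abs(pk$peak_s - vertex_t), 1e-6)
  expect_lt(abs(pk$peak_dff - vertex_v), 1e-6)
  expect_gte(pk$peak_dff, max(v))
  # peak exactly on a sample of a symmetric pulse stays put
  v2 <- exp(-(t - 10)^2 / 4)
  tr2 <- csd_trace(v2, rate_hz = rate, unit = "dff")
  pk2 <- peak_by_spline(tr2, list(peak_s = 10))
  expect_equal(pk2$peak_s, 10, tolerance = 1e-7)
  expect_equal(pk2$peak_dff, 1, tolerance = 1e-9)
})

test_that("half-maximum times obey triangle geometry and a dense-grid oracle", {
  # symmetric triangular pulse: peak A at p, base width W -> crossings p -/+ W/4
  rate <- 10; A <- 2; p <- 50; W <- 40
  t <- seq(0, 100 - 0.1, by = 0.1)
  v <- pmax(0, A * (1 - abs(t - p) / (W / 2)))
  tr <- csd_trace(v, rate_hz = rate, unit = "dff")
  hm <- half_max_times(tr, list(peak_s = p, peak_dff = A))
  expect_equal(unname(hm["arrival_s"]), p - W / 4, tolerance = 1e-9)
  expect_equal(unname(hm["passage_s"]), p + W / 4, tolerance = 1e-9)
  # random smooth pulse against a dense-grid brute-force oracle
  f <- function(x) 1.7 * exp(-(x - 42.3)^2 / 55)
  v2 <- f(t)
  tr2 <- csd_trace(v2, rate_hz = rate, unit = "dff")
  hm2 <- half_max_times(tr2, list(peak_s = 42.3, peak_dff = 1.7))
  dense <- seq(0, 100, by = 1e-4)
  dv <- f(dense)
  oracle_arr <- dense[min(which(dv >= 0.85))]
  oracle_pas <- dense[max(which(dv >= 0.85))]
  expect_lt(abs(hm2["arrival_s"] - oracle_arr), 0.1)
  expect_lt(abs(hm2["passage_s"] - oracle_pas), 0.1)
})

test_that("events on a clean trapezoid pulse carry the planted timing", {
  tr <- pulse_trace(noise = 0.004, seed = 8)
  ev <- detect_csd_events(tr, time_window(5, 45))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$peak_dff, 2, tolerance = 0.01)
  # supra-half-max duration = rise/2 + hold + fall/2 = 50
  expect_equal(ev$duration_s, 50, tolerance = 0.005)
  expect_event_ordering(ev)
})

test_that("wave_speed converts transits and flags unmatched waves", {
  near <- data.frame(arrival_s = c(10, 300))
  far <- data.frame(arrival_s = c(10 + 27.2727272727, 290))
  expect_warning(sp <- wave_speed(near, far, 2.0), "non-positive")
  expect_equal(sp$speed_mm_per_min[1], 4.4, tolerance = 1e-9)
  expect_false(sp$matched[2])
  sp2 <- wave_speed(data.frame(arrival_s = 0), data.frame(arrival_s = 60), 2.0)
  expect_equal(sp2$speed_mm_per_min, 2.0)
})

test_that("inter-event intervals are onset diffs", {
  ev <- structure(data.frame(onset_s = c(10, 291.1, 600)),
                  class = c("csd_events", "data.frame"))
  expect_equal(inter_event_interval(ev), c(281.1, 308.9))
  expect_equal(inter_event_interval(ev[1, , drop = FALSE]), numeric(0))
})

test_that("band RMS matches sinusoid identity, kills DC, matches its oracle", {
  rate <- 10
  t <- seq(0, 600 - 1 / rate, by = 1 / rate)
  A <- 0.05
  tr <- csd_trace(A * sin(2 * pi * 1 * t), rate_hz = rate, unit = "dff")
  rms <- band_rms_amplitude(tr)
  expect_equal(length(rms$values), 2)
  expect_true(all(abs(rms$values - A / sqrt(2)) / (A / sqrt(2)) < 0.02))
  expect_equal(trace_times(rms), c(150, 450))
  # DC only -> ~0 (DC is outside the band)
  dc <- csd_trace(rep(0.7, 6000), rate_hz = rate, unit = "dff")
  expect_lt(max(band_rms_amplitude(dc)$values), 1e-3)
  # white noise: windowed RMS equals the sqrt-mean-square of the filtered signal
  set.seed(2)
  x <- rnorm(6000, 0, 0.03)
  trn <- csd_trace(x, rate_hz = rate, unit = "dff")
  rn <- band_rms_amplitude(trn)
  y <- bandpass_zero_phase(trn)$values
  expect_equal(rn$values, c(sqrt(mean(y[1:3000]^2)), sqrt(mean(y[3001:6000]^2))))
  # gain linearity: scaling the input by c scales the output by c
  r3 <- band_rms_amplitude(csd_trace(3 * x, rate_hz = rate, unit = "dff"))
  expect_equal(r3$values, 3 * rn$values, tolerance = 1e-12)
})

test_that("recovery curves normalize to the 10-min pre-KCl reference", {
  amp <- csd_trace(rep(0.03, 6), rate_hz = 1 / 300, t0_s = -450, unit = "dff")
  rc <- recovery_curve(amp, time_window(0, 600))
  expect_true(all(rc$rel_amplitude == 1))
  expect_error(recovery_curve(csd_trace(rep(0.03, 3), 1 / 300, t0_s = 150,
                                        unit = "dff"), time_window(0, 600)),
               "reference")
})

test_that("suppression-recovery scenario yields ~50% amplitude at tau*ln2 and a
           recoverable time constant", {
  tau <- 600
  s <- widefield_scenario(grid = 16, duration_s = 3600, t0_s = -600,
                          wave_onsets_s = 60, speed_mm_per_min = 4.4,
                          suppression_recovery_s = tau,
                          post_csd_baseline_drop_frac = 0,
                          noise_sd_dff = 0, geometry = "radial",
                          truncate_ok = TRUE, seed = 2)
  sim <- simulate_widefield(s)
  roi <- pixel_rect(7, 7, 3, 3)
  tr <- extract_roi_trace(sim$movie, roi)
  dff <- compute_dff(tr, 0)
  amp <- band_rms_amplitude(dff)
  rc <- recovery_curve(amp, time_window(0, 600))
  # each post-passage window's relative amplitude matches the dense-grid
  # RMS of the gate profile gate(t) = 1 - exp(-(t - passage)/tau)
  pass <- wavefront_arrival(s, 8, 8) + 1 + s$wave_duration_s
  for (i in which(rc$time_s > pass + 150)) {
    tw <- seq(rc$time_s[i] - 150, rc$time_s[i] + 150, by = 0.01)
    gate <- ifelse(tw < pass, 1, 1 - exp(-(tw - pass) / tau))
    expect_equal(rc$rel_amplitude[i], sqrt(mean(gate^2)), tolerance = 0.05)
  }
  # fitted tau from the gated windows within 10%
  post <- rc[rc$time_s > pass + 150 & rc$rel_amplitude > 0.5 &
               rc$rel_amplitude < 0.999, ]
  fit <- lm(log(1 - post$rel_amplitude) ~ post$time_s)
  expect_equal(-1 / unname(coef(fit)[2]), tau, tolerance = 0.1)
  # late windows approach full recovery (the ~100% regime)
  expect_gt(tail(rc$rel_amplitude, 1), 0.9)
})

test_that("estimated speed is invariant to uniform intensity scaling", {
  s <- widefield_scenario(grid = 32, field_mm = 6.4, duration_s = 260, t0_s = -120,
                          wave_onsets_s = 40, speed_mm_per_min = 4.4,
                          noise_sd_dff = 0, geometry = "planar",
                          truncate_ok = TRUE, seed = 6)
  sim <- simulate_widefield(s)
  rois <- speed_rois(s)
  est <- function(movie) {
    ne <- detect_csd_events(compute_dff(extract_roi_trace(movie, rois$near), 0),
                            time_window(-60, -20))
    fe <- detect_csd_events(compute_dff(extract_roi_trace(movie, rois$far), 0),
                            time_window(-60, -20))
    wave_speed(ne, fe, rois$separation_mm)$speed_mm_per_min
  }
  v1 <- est(sim$movie)
  scaled <- sim$movie
  scaled$data <- scaled$data * 37.5
  expect_equal(est(scaled), v1, tolerance = 1e-12)
  expect_equal(v1, 4.4, tolerance = 0.02)
})

test_that("speed recovery holds across the physiological 2-6 mm/min range", {
  errs <- vapply(seq(2, 6, length.out = 5), function(v) {
    s <- widefield_scenario(grid = 32, field_mm = 6.4, duration_s = 200 + 600 / v,
                            t0_s = -120, wave_onsets_s = 40, speed_mm_per_min = v,
                            noise_sd_dff = 0.01, geometry = "planar",
                            truncate_ok = TRUE, seed = round(100 * v))
    sim <- simulate_widefield(s)
    rois <- speed_rois(s)
    ne <- detect_csd_events(compute_dff(extract_roi_trace(sim$movie, rois$near), 0),
                            time_window(-60, -20))
    fe <- detect_csd_events(compute_dff(extract_roi_trace(sim$movie, rois$far), 0),
                            time_window(-60, -20))
    abs(wave_speed(ne, fe, rois$separation_mm)$speed_mm_per_min[1] - v) / v
  }, 0)
  expect_lt(median(errs), 0.03)
})
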
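# Shared fixtures, all generated in code.

# deterministic small integer movie for I/O and binning tests
fixture_movie <- function(nf = 10, nr = 8, nc = 8, seed = 42) {
  set.seed(seed)
  csd_movie(array(sample(0:65535, nf * nr * nc, replace = TRUE), c(nf, nr, nc)),
            frame_rate_hz = 10, pixel_pitch_mm = 0.02, t0_s = 0)
}

# a clean trapezoid ΔF/F pulse trace on a flat baseline
pulse_trace <- function(rate = 10, dur = 200, onset = 60, rise = 2, hold = 48,
                        fall = 2, peak = 2, baseline = 0, noise = 0, seed = 1) {
  t <- (seq_len(dur * rate) - 1) / rate
  rel <- t - onset
  v <- rep(baseline, length(t))
  v[rel >= 0 & rel < rise] <- baseline + peak * rel[rel >= 0 & rel < rise] / rise
  v[rel >= rise & rel < rise + hold] <- baseline + peak
  idx <- rel >= rise + hold & rel < rise + hold + fall
  v[idx] <- baseline + peak * (1 - (rel[idx] - rise - hold) / fall)
  if (noise > 0) { set.seed(seed); v <- v + rnorm(length(v), 0, noise) }
  csd_trace(v, rate_hz = rate, t0_s = 0, unit = "dff")
}

expect_event_ordering <- function(events) {
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    expect_lte(e$onset_s, e$arrival_s + 1e-9)
    expect_lte(e$arrival_s, e$peak_s + 1e-9)
    if (!is.na(e$passage_s)) expect_lte(e$peak_s, e$passage_s + 1e-9)
  }
}
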
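#' Convert a raw fluorescence trace to ΔF/F
#'
#' The baseline F is the mean intensity over the 40-s period ending 20 s
#' before KCl application, i.e. `[kcl - 60, kcl - 20)`; the output is
#' `(x - F) / F`.
#'
#' @param t A `csd_trace` covering at least `[kcl_time_s - 60, kcl_time_s)`.
#' @param kcl_time_s Time of KCl application (s) on the trace clock.
#' @return A `csd_trace` with unit `dff`.
#' @export
compute_dff <- function(t, kcl_time_s) {
  stopifnot(inherits(t, "csd_trace"))
  tt <- trace_times(t)
  if (t$t0_s > kcl_time_s - 60 || max(tt) < kcl_time_s - 1 / t$rate_hz)
    stop("trace must cover [kcl_time_s - 60, kcl_time_s)")
  idx <- window_indices(t, time_window(kcl_time_s - 60, kcl_time_s - 20))
  if (length(idx) < 1) stop("no samples in the baseline window")
  f0 <- mean(t$values[idx])
  if (f0 <= 0) stop("baseline F <= 0; cannot form ΔF/F")
  out <- csd_trace((t$values - f0) / f0, rate_hz = t$rate_hz,
                   t0_s = t$t0_s, unit = "dff")
  attr(out, "baseline_f") <- f0
  out
}

#' Detect CSD events on a ΔF/F trace
#'
#' CSD onset is the first upward crossing of `baseline mean + k_sd * SD`
#' (default +5 SD, statistics from `baseline_window`). An event lasts until
#' the signal falls below half of that event's peak; threshold crossings
#' inside an ongoing event start no new event, and a new event additionally
#' requires a fresh crossing at least `refractory_s` after the previous
#' event's end (well below the shortest reported ~280-s inter-CSD
#' interval). Each event's peak is refined by cubic spline interpolation
#' and its half-maximum arrival/passage times by linear interpolation.
#'
#' @param t A `csd_trace` (unit `dff`).
#' @param baseline_window [time_window()] for threshold statistics; must
#'   have nonzero variance.
#' @param k_sd Threshold in baseline SDs above the baseline mean.
#' @param refractory_s Minimum gap between an event's end and the next
#'   event's threshold crossing (s).
#' @param roi_id Label carried into the result.
#' @return A `csd_events` data frame with one row per event: `roi_id`,
#'   `onset_s`, `arrival_s`, `peak_s`, `peak_dff`, `passage_s`,
#'   `duration_s`. Events still above half-maximum at the end of the trace
#'   have `NA` passage/duration and raise a warning. Attributes `threshold`,
#'   `baseline_mean`, `baseline_sd` record the detection parameters.
#' @export
detect_csd_events <- function(t, baseline_window, k_sd = 5, refractory_s = 10,
                              roi_id = "roi") {
  stopifnot(inherits(t, "csd_trace"), inherits(baseline_window, "time_window"))
  bidx <- window_indices(t, baseline_window)
  if (length(bidx) < 2) stop("baseline window contains < 2 samples")
  mu <- mean(t$values[bidx])
  sdev <- stats::sd(t$values[bidx])
  if (sdev == 0) stop("zero-variance baseline; threshold undefined")
  thr <- mu + k_sd * sdev
  v <- t$values
  tt <- trace_times(t)
  n <- length(v)

  rows <- list()
  i <- 1L
  min_next <- -Inf  # earliest time a fresh crossing may start an event
  while (i <= n) {
    above <- which(v[i:n] > thr)
    if (length(above) == 0) break
    j <- i + above[1] - 1L
    if (tt[j] < min_next) { i <- j + 1L; next }
    onset <- if (j == 1L) tt[1] else cross_time(tt, v, j - 1L, thr)
    # walk forward tracking the running maximum until below half of it
    pk <- v[j]; pk_i <- j; k <- j
    while (k < n) {
      k <- k + 1L
      if (v[k] > pk) { pk <- v[k]; pk_i <- k }
      if (k > pk_i && v[k] < pk / 2) break
    }
    complete <- v[k] < pk / 2
    sp <- spline_peak(t, pk_i)
    hm <- halfmax_crossings(t, sp$peak_s, sp$peak_dff)
    rows[[length(rows) + 1L]] <- data.frame(
      roi_id = roi_id, onset_s = onset, arrival_s = unname(hm["arrival_s"]),
      peak_s = sp$peak_s, peak_dff = sp$peak_dff,
      passage_s = if (complete) unname(hm["passage_s"]) else NA_real_,
      duration_s = if (complete) unname(hm["passage_s"] - hm["arrival_s"]) else NA_real_,
      row.names = NULL)
    if (!complete) {
      warning("event still above half-maximum at trace end; passage undefined")
      break
    }
    min_next <- tt[k] + refractory_s
    i <- k + 1L
  }
  ev <- if (length(rows)) do.call(rbind, rows) else
    data.frame(roi_id = character(0), onset_s = numeric(0), arrival_s = numeric(0),
               peak_s = numeric(0), peak_dff = numeric(0), passage_s = numeric(0),
               duration_s = numeric(0))
  class(ev) <- c("csd_events", "data.frame")
  attr(ev, "threshold") <- thr
  attr(ev, "baseline_mean") <- mu
  attr(ev, "baseline_sd") <- sdev
  ev
}

#' @export
print.csd_events <- function(x, ...) {
  cat(sprintf("<csd_events> %d event(s), threshold %.4g\n",
              nrow(x), attr(x, "threshold")))
  if (nrow(x)) print.data.frame(x, digits = 5)
  invisible(x)
}

# spline peak refinement around a discrete argmax index
spline_peak <- function(t, peak_index, half_window_s = 2) {
  v <- t$values
  tt <- trace_times(t)
  hw <- round(half_window_s * t$rate_hz)
  lo <- peak_index - hw
  hi <- peak_index + hw
  if (lo < 1 || hi > length(v)) {
    warning("peak window truncated by trace edge; using discrete maximum")
    lo <- max(1L, lo); hi <- min(length(v), hi)
    if (hi - lo < 4) return(list(peak_s = tt[peak_index], peak_dff = v[peak_index]))
  }
  f <- stats::splinefun(tt[lo:hi], v[lo:hi], method = "fmm")
  opt <- stats::optimize(f, c(tt[lo], tt[hi]), maximum = TRUE, tol = 1e-9)
  if (opt$objective >= v[peak_index])
    list(peak_s = opt$maximum, peak_dff = opt$objective)
  else
    list(peak_s = tt[peak_index], peak_dff = v[peak_index])
}

#' Refine an event peak by cubic spline interpolation
#'
#' Fits a cubic interpolating spline to a window of `+/- half_window_s`
#' around the event's discrete maximum and returns the continuous maximum,
#' which is never below the discrete one. A window truncated by the trace
#' edge falls back to the discrete maximum with a warning.
#'
#' @param t The `csd_trace` the event was detected on.
#' @param event One row of a `csd_events` frame (or anything with `peak_s`).
#' @param half_window_s Half-width of the spline window (s).
#' @return List with `peak_s`, `peak_dff`.
#' @export
peak_by_spline <- function(t, event, half_window_s = 2) {
  stopifnot(inherits(t, "csd_trace"))
  idx <- round((event$peak_s - t$t0_s) * t$rate_hz) + 1L
  idx <- max(1L, min(length(t$values), idx))
  # snap to the discrete argmax in the immediate neighbourhood
  nb <- max(1L, idx - 2L):min(length(t$values), idx + 2L)
  idx <- nb[which.max(t$values[nb])]
  spline_peak(t, idx, half_window_s)
}

# half-maximum crossings around a known peak, by linear interpolation
halfmax_crossings <- function(t, peak_s, peak_dff) {
  v <- t$values
  tt <- trace_times(t)
  level <- peak_dff / 2
  pk_i <- which.min(abs(tt - peak_s))
  arrival <- NA_real_
  i <- pk_i
  while (i > 1L) {
    i <- i - 1L
    if (v[i] < level) { arrival <- cross_time(tt, v, i, level); break }
  }
  if (is.na(arrival)) arrival <- tt[1]
  passage <- NA_real_
  i <- pk_i
  while (i < length(v)) {
    i <- i + 1L
    if (v[i] < level) { passage <- cross_time(tt, v, i - 1L, level); break }
  }
  c(arrival_s = arrival, passage_s = passage)
}

#' Half-maximum arrival and passage times of an event
#'
#' Arrival is the last upward crossing of half the peak amplitude before
#' the peak; passage is the first downward crossing after it, both by
#' linear interpolation between samples. A signal that never falls below
#' half-maximum before the trace ends yields `NA` passage with a warning.
#'
#' @param t The `csd_trace`.
#' @param event One event row (needs `peak_s`, `peak_dff`).
#' @return Named vector `arrival_s`, `passage_s`.
#' @export
half_max_times <- function(t, event) {
  stopifnot(inherits(t, "csd_trace"))
  out <- halfmax_crossings(t, event$peak_s, event$peak_dff)
  if (is.na(out["passage_s"]))
    warning("signal never subsides below half-maximum before trace end")
  out
}

#' Propagation speed from two ROIs
#'
#' Speed is the ROI separation divided by the half-maximum arrival-time
#' difference between a near ROI (close to the KCl site) and a far ROI
#' 2 mm anterior, per matched wave. Waves are matched by order of
#' occurrence; a non-positive transit time leaves the wave unmatched
#' (`NA` speed) with a warning.
#'
#' @param near,far `csd_events` frames from the two ROIs.
#' @param separation_mm ROI center separation (mm).
#' @return `data.frame` with `wave`, `near_arrival_s`, `far_arrival_s`,
#'   `transit_s`, `speed_mm_per_min`, `matched`.
#' @export
wave_speed <- function(near, far, separation_mm = 2.0) {
  n <- max(nrow(near), nrow(far))
  if (n == 0) return(data.frame(wave = integer(0), near_arrival_s = numeric(0),
                                far_arrival_s = numeric(0), transit_s = numeric(0),
                                speed_mm_per_min = numeric(0), matched = logical(0)))
  out <- data.frame(wave = seq_len(n), near_arrival_s = NA_real_,
                    far_arrival_s = NA_real_, transit_s = NA_real_,
                    speed_mm_per_min = NA_real_, matched = FALSE)
  for (w in seq_len(min(nrow(near), nrow(far)))) {
    a1 <- near$arrival_s[w]; a2 <- far$arrival_s[w]
    out$near_arrival_s[w] <- a1
    out$far_arrival_s[w] <- a2
    transit <- a2 - a1
    out$transit_s[w] <- transit
    if (is.na(transit) || transit <= 0) {
      warning(sprintf("wave %d: non-positive transit time; unmatched", w))
    } else {
      out$speed_mm_per_min[w] <- separation_mm / transit * 60
      out$matched[w] <- TRUE
    }
  }
  out
}

#' Inter-event intervals
#'
#' Successive onset-to-onset differences; fewer than two events yield an
#' empty vector.
#'
#' @param events A `csd_events` frame (rows in time order).
#' @return Numeric vector of intervals (s).
#' @export
inter_event_interval <- function(events) {
  if (nrow(events) < 2) return(numeric(0))
  diff(events$onset_s)
}

#' Zero-phase Butterworth band-pass of a trace
#'
#' Forward-backward (zero-phase) filtering with odd-reflection padding at
#' both ends; the pad length covers several periods of the low band edge so
#' start-up transients do not leak into the output. Zero phase preserves
#' the event timing used elsewhere in the pipeline.
#'
#' @param t A `csd_trace`.
#' @param band_hz Pass band `c(low, high)` in Hz.
#' @param order Butterworth prototype order.
#' @return The filtered `csd_trace`.
#' @export
bandpass_zero_phase <- function(t, band_hz = c(0.1, 3), order = 2) {
  stopifnot(inherits(t, "csd_trace"))
  if (t$rate_hz <= 2 * band_hz[2])
    stop("sampling rate too low for the requested band")
  bf <- signal::butter(order, band_hz / (t$rate_hz / 2), type = "pass")
  x <- t$values
  n <- length(x)
  np <- min(n - 1L, ceiling(3 / band_hz[1] * t$rate_hz))
  head_pad <- 2 * x[1] - x[(np + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - np)]
  y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))[(np + 1):(np + n)]
  out <- t
  out$values <- y
  out
}

#' Band-limited RMS amplitude in sliding windows
#'
#' Applies a zero-phase (forward-backward) second-order Butterworth
#' band-pass, then computes the root mean square over consecutive
#' non-overlapping windows. The default 0.1-3 Hz band and 5-min windows
#' quantify slow-wave (UP/DOWN state) activity amplitude.
#'
#' @param t A `csd_trace` with `rate_hz > 2 * band_hz[2]`.
#' @param band_hz Pass band `c(low, high)` in Hz.
#' @param window_s Window length (s).
#' @param order Butterworth prototype order.
#' @return A `csd_trace` of per-window RMS values (rate `1 / window_s`),
#'   timestamped at window centers; unit inherited.
#' @export
band_rms_amplitude <- function(t, band_hz = c(0.1, 3), window_s = 300, order = 2) {
  stopifnot(inherits(t, "csd_trace"))
  if (t$rate_hz <= 2 * band_hz[2])
    stop("sampling rate too low for the requested band")
  wlen <- round(window_s * t$rate_hz)
  if (length(t$values) < wlen) stop("trace shorter than one window")
  y <- bandpass_zero_phase(t, band_hz, order)$values
  nw <- length(y) %/% wlen
  rms <- vapply(seq_len(nw), function(k)
    sqrt(mean(y[((k - 1) * wlen + 1):(k * wlen)]^2)), 0)
  csd_trace(rms, rate_hz = 1 / window_s,
            t0_s = t$t0_s + window_s / 2, unit = t$unit)
}

#' Recovery curve of windowed amplitude relative to the pre-KCl reference
#'
#' Each windowed amplitude is divided by the mean amplitude over the 10-min
#' period immediately preceding KCl application, so the pre-KCl level maps
#' to 1.0 (100%).
#'
#' @param amp Amplitude trace from [band_rms_amplitude()]; must cover
#'   `[kcl start - reference_s, kcl start)`.
#' @param kcl_window The KCl exposure [time_window()].
#' @param reference_s Length of the pre-KCl reference period (s).
#' @return A `recovery_curve` data frame with `time_s`, `rel_amplitude`;
#'   the reference window is attached as an attribute.
#' @export
recovery_curve <- function(amp, kcl_window, reference_s = 600) {
  stopifnot(inherits(amp, "csd_trace"), inherits(kcl_window, "time_window"))
  ref_win <- time_window(kcl_window$start_s - reference_s, kcl_window$start_s)
  idx <- window_indices(amp, ref_win)
  if (length(idx) < 1) stop("amplitude trace does not cover the pre-KCl reference")
  ref <- mean(amp$values[idx])
  if (ref <= 0) stop("zero reference amplitude")
  out <- data.frame(time_s = trace_times(amp), rel_amplitude = amp$values / ref)
  class(out) <- c("recovery_curve", "data.frame")
  attr(out, "reference_window") <- ref_win
  attr(out, "reference_amplitude") <- ref
  out
}

#' @export
print.recovery_curve <- function(x, ...) {
  rw <- attr(x, "reference_window")
  cat(sprintf("<recovery_curve> %d windows, reference [%g, %g) s\n",
              nrow(x), rw$start_s, rw$end_s))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' @export
plot.recovery_curve <- function(x, ...) {
  graphics::plot(x$time_s, 100 * x$rel_amplitude, type = "b",
                 xlab = "time (s)", ylab = "relative amplitude (%)", ...)
  graphics::abline(h = 100, lty = 2)
  invisible(x)
}
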
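#' Fit an ion-selective electrode calibration curve
#'
#' Ordinary least squares of measured voltage against log10 of the known
#' K+ concentration (the ionophore response is Nernstian: voltage linear in
#' the log of activity, ~58 mV per decade at body temperature). A raw
#' linear-in-mM mode is exposed for comparison.
#'
#' @param table `data.frame` with columns `conc_mM`, `voltage_mV`; at least
#'   3 distinct positive concentrations.
#' @param mode `"log10"` (default) or `"linear"` regressor scale.
#' @return An object of class `calibration_curve` with elements
#'   `slope_mV_per_decade` (per mM in linear mode), `offset_mV`,
#'   `r_squared`, `conc_range_mM`, `mode`.
#' @export
fit_calibration <- function(table, mode = c("log10", "linear")) {
  mode <- match.arg(mode)
  if (!all(c("conc_mM", "voltage_mV") %in% names(table)))
    stop("table must have columns conc_mM and voltage_mV")
  if (any(table$conc_mM <= 0)) stop("concentrations must be positive")
  if (length(unique(table$conc_mM)) < 3)
    stop("calibration requires >= 3 distinct concentrations")
  x <- if (mode == "log10") log10(table$conc_mM) else table$conc_mM
  fit <- stats::lm(table$voltage_mV ~ x)
  ss_tot <- sum((table$voltage_mV - mean(table$voltage_mV))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(slope_mV_per_decade = unname(stats::coef(fit)[2]),
                 offset_mV = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 conc_range_mM = range(table$conc_mM),
                 mode = mode),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> V = %.4g + %.4g * %s, R^2 = %.6f, range [%g, %g] mM\n",
              x$offset_mV, x$slope_mV_per_decade,
              if (x$mode == "log10") "log10([K+])" else "[K+]",
              x$r_squared, x$conc_range_mM[1], x$conc_range_mM[2]))
  invisible(x)
}

#' @export
coef.calibration_curve <- function(object, ...) {
  c(offset_mV = object$offset_mV, slope_mV_per_decade = object$slope_mV_per_decade)
}

#' Predict electrode voltage for given concentrations
#'
#' @param object A `calibration_curve`.
#' @param conc_mM Concentrations (mM).
#' @param ... Unused.
#' @return Predicted voltages (mV).
#' @export
predict.calibration_curve <- function(object, conc_mM, ...) {
  x <- if (object$mode == "log10") log10(conc_mM) else conc_mM
  object$offset_mV + object$slope_mV_per_decade * x
}

#' Invert a calibration curve: voltage to concentration
#'
#' @param cal A `calibration_curve`.
#' @param voltage_mV Voltages (mV).
#' @return Concentrations (mM).
#' @export
concentration_from_voltage <- function(cal, voltage_mV) {
  if (cal$slope_mV_per_decade == 0) stop("zero calibration slope")
  x <- (voltage_mV - cal$offset_mV) / cal$slope_mV_per_decade
  if (cal$mode == "log10") 10^x else x
}

#' Subtract the reference LFP from the ion-electrode recording
#'
#' Removes the common-mode field potential so only the Nernstian component
#' remains. Traces must share rate, start time and length; resample/align
#' first otherwise.
#'
#' @param k_electrode,ref_lfp `csd_trace`s in mV.
#' @return Their elementwise difference as a `csd_trace` (mV).
#' @export
subtract_reference <- function(k_electrode, ref_lfp) {
  stopifnot(inherits(k_electrode, "csd_trace"), inherits(ref_lfp, "csd_trace"))
  if (k_electrode$rate_hz != ref_lfp$rate_hz)
    stop("rate mismatch between electrodes")
  if (length(k_electrode$values) != length(ref_lfp$values) ||
      k_electrode$t0_s != ref_lfp$t0_s)
    stop("traces are not aligned")
  csd_trace(k_electrode$values - ref_lfp$values, rate_hz = k_electrode$rate_hz,
            t0_s = k_electrode$t0_s, unit = "mV")
}

#' Convert an electrode voltage trace to [K+]e at 10 Hz
#'
#' Anti-alias low-pass (block averaging over each decimation window, a
#' moving-average filter whose output is timestamped at the window center)
#' then decimation to `out_rate_hz`, followed by inversion of the
#' calibration. Samples converting outside the calibrated concentration
#' range are flagged per sample (`out_of_range` attribute), not clamped —
#' clamping would silently bias post-CSD peaks.
#'
#' @param v Voltage `csd_trace` (mV); its rate must be an integer multiple
#'   of `out_rate_hz`.
#' @param cal A [fit_calibration()] curve.
#' @param out_rate_hz Output rate (Hz).
#' @return `csd_trace` in mM with attribute `out_of_range` (logical per
#'   sample).
#' @export
to_concentration <- function(v, cal, out_rate_hz = 10) {
  stopifnot(inherits(v, "csd_trace"), inherits(cal, "calibration_curve"))
  factor <- v$rate_hz / out_rate_hz
  if (abs(factor - round(factor)) > 1e-9 || factor < 1)
    stop("input rate must be an integer multiple of out_rate_hz")
  factor <- as.integer(round(factor))
  n <- (length(v$values) %/% factor) * factor
  if (n < factor) stop("trace shorter than one output sample")
  dec <- if (factor > 1) colMeans(matrix(v$values[seq_len(n)], factor)) else v$values
  conc <- concentration_from_voltage(cal, dec)
  t0 <- v$t0_s + (factor - 1) / (2 * v$rate_hz)   # block-center timestamps
  out <- csd_trace(conc, rate_hz = out_rate_hz, t0_s = t0, unit = "mM")
  attr(out, "out_of_range") <- conc < cal$conc_range_mM[1] | conc > cal$conc_range_mM[2]
  out
}

#' Interval summaries of a concentration trace
#'
#' The statistic (median by default, as in 10-min interval summaries of
#' [K+]e) over consecutive non-overlapping intervals, timestamped at
#' interval centers. Only complete intervals are summarized.
#'
#' @param t A `csd_trace` at least one interval long.
#' @param interval_s Interval length (s).
#' @param stat Summary function.
#' @return `data.frame` with `t_center_s`, `value`, `n`.
#' @export
k_summary <- function(t, interval_s = 600, stat = stats::median) {
  stopifnot(inherits(t, "csd_trace"))
  wlen <- round(interval_s * t$rate_hz)
  ni <- length(t$values) %/% wlen
  if (ni < 1) stop("trace shorter than one interval")
  data.frame(
    t_center_s = t$t0_s + (seq_len(ni) - 0.5) * interval_s,
    value = vapply(seq_len(ni), function(k)
      stat(t$values[((k - 1) * wlen + 1):(k * wlen)]), 0),
    n = wlen)
}

#' Whisker-evoked LFP amplitudes
#'
#' Per stimulus: baseline = mean over `[-pre_ms, 0)` ms; amplitude = the
#' magnitude of the deflection from baseline to the response extremum in
#' `(0, post_ms]` ms; latency = time of that extremum. The extremum
#' polarity is auto-detected from the mean response across the reference
#' stimuli (pre-KCl when `reference_window` is given, else all) and held
#' fixed thereafter. Stimuli too close to the trace edges are skipped with
#' a warning.
#'
#' @param lfp LFP `csd_trace` (mV).
#' @param stim_times Stimulus times (s).
#' @param pre_ms,post_ms Baseline and response windows (ms).
#' @param polarity `"auto"`, `"neg"` or `"pos"`.
#' @param reference_window Optional [time_window()] of reference stimuli
#'   for polarity detection.
#' @return `evoked_responses` data frame: `stim_time_s`, `amplitude_mV`,
#'   `latency_s`; attribute `polarity`.
#' @export
evoked_amplitudes <- function(lfp, stim_times, pre_ms = 50, post_ms = 100,
                              polarity = c("auto", "neg", "pos"),
                              reference_window = NULL) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(lfp, "csd_trace"))
  rate <- lfp$rate_hz
  npre <- round(pre_ms / 1000 * rate)
  npost <- round(post_ms / 1000 * rate)
  n <- length(lfp$values)
  idx0 <- round((stim_times - lfp$t0_s) * rate) + 1L
  ok <- idx0 - npre >= 1 & idx0 + npost <= n
  if (any(!ok)) warning(sprintf("%d stimulus(es) too close to trace edge skipped", sum(!ok)))
  stim_times <- stim_times[ok]; idx0 <- idx0[ok]
  if (length(idx0) == 0) stop("no usable stimuli")

  snip <- function(i0) {
    base <- mean(lfp$values[(i0 - npre):(i0 - 1)])
    lfp$values[(i0 + 1):(i0 + npost)] - base
  }
  if (polarity == "auto") {
    ref_ids <- if (is.null(reference_window)) seq_along(idx0) else
      which(stim_times >= reference_window$start_s & stim_times < reference_window$end_s)
    if (length(ref_ids) == 0) ref_ids <- seq_along(idx0)
    mresp <- rowMeans(vapply(idx0[ref_ids], snip, numeric(npost)))
    polarity <- if (abs(min(mresp)) >= abs(max(mresp))) "neg" else "pos"
  }
  res <- t(vapply(idx0, function(i0) {
    d <- snip(i0)
    j <- if (polarity == "neg") which.min(d) else which.max(d)
    c(abs(d[j]), j / rate)
  }, numeric(2)))
  out <- data.frame(stim_time_s = stim_times, amplitude_mV = res[, 1],
                    latency_s = res[, 2])
  class(out) <- c("evoked_responses", "data.frame")
  attr(out, "polarity") <- polarity
  out
}

#' Normalize evoked amplitudes to the pre-KCl reference
#'
#' Mean amplitude per time bin divided by the mean amplitude over the
#' pre-KCl window, so the reference period maps to 1.0.
#'
#' @param resp An [evoked_amplitudes()] frame.
#' @param pre_kcl Pre-KCl reference [time_window()]; must contain at least
#'   one response.
#' @param bin_s Bin width (s); bins are aligned to the end of `pre_kcl`
#'   (the KCl application time).
#' @return A `recovery_curve` data frame (`time_s` at bin centers,
#'   `rel_amplitude`).
#' @export
normalize_evoked <- function(resp, pre_kcl, bin_s = 600) {
  stopifnot(inherits(pre_kcl, "time_window"))
  ref_ids <- resp$stim_time_s >= pre_kcl$start_s & resp$stim_time_s < pre_kcl$end_s
  if (!any(ref_ids)) stop("no responses in the pre-KCl reference window")
  ref <- mean(resp$amplitude_mV[ref_ids])
  if (ref <= 0) stop("zero reference amplitude")
  bin <- floor((resp$stim_time_s - pre_kcl$end_s) / bin_s)
  agg <- stats::aggregate(resp$amplitude_mV, by = list(bin = bin), FUN = mean)
  out <- data.frame(time_s = pre_kcl$end_s + (agg$bin + 0.5) * bin_s,
                    rel_amplitude = agg$x / ref)
  class(out) <- c("recovery_curve", "data.frame")
  attr(out, "reference_window") <- pre_kcl
  attr(out, "reference_amplitude") <- ref
  out
}

#' Relation between evoked-LFP recovery and [K+]e
#'
#' Pairs each amplitude bin with the nearest [K+]e summary bin and reports
#' the Spearman rank correlation — the inverse relationship between
#' neural-activity recovery and residual extracellular potassium.
#'
#' @param amp A `recovery_curve`.
#' @param k A [k_summary()] table.
#' @return List with `pairs` (data frame `time_s`, `rel_amplitude`,
#'   `k_mM`), `rho`, `p_value`.
#' @export
lfp_k_relation <- function(amp, k) {
  if (nrow(amp) < 1 || nrow(k) < 1) stop("empty inputs")
  nearest <- vapply(amp$time_s, function(tm) which.min(abs(k$t_center_s - tm)), 0L)
  pairs <- data.frame(time_s = amp$time_s, rel_amplitude = amp$rel_amplitude,
                      k_mM = k$value[nearest])
  if (nrow(pairs) < 3) stop("fewer than 3 aligned pairs")
  sr <- spearman_rank(pairs$rel_amplitude, pairs$k_mM)
  list(pairs = pairs, rho = sr$rho, p_value = sr$p_value)
}
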
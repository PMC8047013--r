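#' Electrophysiology scenario
#'
#' Ground truth for synthetic double-barrel K+ electrode recordings. The
#' true extracellular potassium concentration sits at `k_baseline_mM`
#' before KCl, ramps linearly to `k_peak_mM` across the KCl window, and
#' decays exponentially back toward baseline with time constant
#' `k_clearance_tau_s` after KCl removal. The ion-selective barrel reads a
#' Nernstian voltage (`offset + slope * log10([K+])`) plus the common-mode
#' LFP; the reference barrel reads the common-mode LFP alone: a slow-wave
#' sinusoid whose amplitude is gated down while [K+] is high (spontaneous
#' LFP is low during the K+ elevation), plus whisker-evoked deflections
#' every `evoked_every_s` that are attenuated after CSD and recover
#' exponentially.
#'
#' @param rate_hz Native sampling rate (Hz). Desk-scale default 1 kHz; the
#'   conversion path still exercises resampling to 10 Hz.
#' @param duration_s Recording length from `t0_s` (s).
#' @param t0_s Recording start relative to KCl application (s).
#' @param kcl_window [time_window()] of KCl exposure.
#' @param k_baseline_mM,k_peak_mM Baseline and peak [K+]e (mM).
#' @param k_clearance_tau_s Clearance time constant (s).
#' @param nernst_slope_mV_per_decade,nernst_offset_mV Electrode response.
#' @param lfp_slowwave_freq_hz,lfp_slowwave_rms_mV Slow-wave LFP frequency
#'   and ungated RMS amplitude.
#' @param evoked_every_s Whisker air-puff interval (s).
#' @param evoked_amp_mV Pre-CSD evoked deflection depth (negative-going).
#' @param evoked_width_s Deflection width (s).
#' @param evoked_attenuation_frac Fractional post-CSD attenuation of the
#'   evoked amplitude (0.5 = attenuated to 50%).
#' @param evoked_recovery_tau_s Recovery time constant of the evoked
#'   amplitude after KCl application (s).
#' @param noise_sd_mV Gaussian sensor noise SD per electrode (mV).
#' @param seed Integer RNG seed.
#' @return An object of class `ephys_scenario`.
#' @export
ephys_scenario <- function(rate_hz = 1000, duration_s = 4800, t0_s = -600,
                           kcl_window = time_window(0, 600),
                           k_baseline_mM = 3.5, k_peak_mM = 30,
                           k_clearance_tau_s = 900,
                           nernst_slope_mV_per_decade = 58,
                           nernst_offset_mV = 0,
                           lfp_slowwave_freq_hz = 1,
                           lfp_slowwave_rms_mV = 0.2,
                           evoked_every_s = 30, evoked_amp_mV = 0.4,
                           evoked_width_s = 0.03,
                           evoked_attenuation_frac = 0.5,
                           evoked_recovery_tau_s = 1200,
                           noise_sd_mV = 0.01, seed = 1L) {
  if (k_baseline_mM <= 0) stop("k_baseline_mM must be > 0")
  if (k_clearance_tau_s <= 0) stop("k_clearance_tau_s must be > 0")
  if (nernst_slope_mV_per_decade <= 0) stop("nernst slope must be > 0")
  structure(list(rate_hz = rate_hz, duration_s = duration_s, t0_s = t0_s,
                 kcl_window = kcl_window, k_baseline_mM = k_baseline_mM,
                 k_peak_mM = k_peak_mM, k_clearance_tau_s = k_clearance_tau_s,
                 nernst_slope_mV_per_decade = nernst_slope_mV_per_decade,
                 nernst_offset_mV = nernst_offset_mV,
                 lfp_slowwave_freq_hz = lfp_slowwave_freq_hz,
                 lfp_slowwave_rms_mV = lfp_slowwave_rms_mV,
                 evoked_every_s = evoked_every_s, evoked_amp_mV = evoked_amp_mV,
                 evoked_width_s = evoked_width_s,
                 evoked_attenuation_frac = evoked_attenuation_frac,
                 evoked_recovery_tau_s = evoked_recovery_tau_s,
                 noise_sd_mV = noise_sd_mV, seed = as.integer(seed)),
            class = "ephys_scenario")
}

#' True [K+]e profile of a scenario
#'
#' @param s An `ephys_scenario`.
#' @param t Times (s) at which to evaluate.
#' @return [K+]e in mM.
#' @export
k_true <- function(s, t) {
  stopifnot(inherits(s, "ephys_scenario"))
  w <- s$kcl_window
  dk <- s$k_peak_mM - s$k_baseline_mM
  k <- rep(s$k_baseline_mM, length(t))
  inw <- t >= w$start_s & t < w$end_s
  k[inw] <- s$k_baseline_mM + dk * (t[inw] - w$start_s) / (w$end_s - w$start_s)
  post <- t >= w$end_s
  k[post] <- s$k_baseline_mM + dk * exp(-(t[post] - w$end_s) / s$k_clearance_tau_s)
  k
}

#' True evoked-amplitude scaling profile
#'
#' 1 before KCl application; `1 - attenuation * exp(-t / recovery_tau)`
#' afterwards.
#'
#' @param s An `ephys_scenario`.
#' @param t Stimulus times (s).
#' @return Scale factors in (0, 1].
#' @export
evoked_scale <- function(s, t) {
  sc <- rep(1, length(t))
  post <- t >= s$kcl_window$start_s
  sc[post] <- 1 - s$evoked_attenuation_frac * exp(-(t[post] - s$kcl_window$start_s) /
                                                    s$evoked_recovery_tau_s)
  sc
}

#' Simulate double-barrel K+ electrode recordings
#'
#' @param s An [ephys_scenario()].
#' @return List with `k_voltage` (ion barrel, mV), `ref_lfp` (reference
#'   barrel, mV), `stim_times` (s) and `truth` (the scenario plus the true
#'   per-stimulus amplitude scale).
#' @export
simulate_ephys <- function(s) {
  stopifnot(inherits(s, "ephys_scenario"))
  n <- round(s$duration_s * s$rate_hz)
  tt <- s$t0_s + (seq_len(n) - 1) / s$rate_hz
  k <- k_true(s, tt)
  nernst <- s$nernst_offset_mV + s$nernst_slope_mV_per_decade * log10(k)

  gate <- pmin(1, s$k_baseline_mM / k)
  lfp <- sqrt(2) * s$lfp_slowwave_rms_mV * sin(2 * pi * s$lfp_slowwave_freq_hz * tt) * gate

  first_stim <- ceiling(s$t0_s / s$evoked_every_s) * s$evoked_every_s
  stim_times <- seq(first_stim, s$t0_s + s$duration_s - 1, by = s$evoked_every_s)
  scale <- evoked_scale(s, stim_times)
  wlen <- round(s$evoked_width_s * s$rate_hz)
  template <- -s$evoked_amp_mV * sin(pi * seq_len(wlen) / (wlen + 1))
  for (j in seq_along(stim_times)) {
    i0 <- round((stim_times[j] - s$t0_s) * s$rate_hz) + 1L
    idx <- i0:min(n, i0 + wlen - 1L)
    if (length(idx) > 0 && i0 >= 1) lfp[idx] <- lfp[idx] + scale[j] * template[seq_along(idx)]
  }

  noise <- if (s$noise_sd_mV > 0)
    with_seed(s$seed, matrix(stats::rnorm(2 * n, 0, s$noise_sd_mV), n, 2))
  else matrix(0, n, 2)

  list(k_voltage = csd_trace(nernst + lfp + noise[, 1], rate_hz = s$rate_hz,
                             t0_s = s$t0_s, unit = "mV"),
       ref_lfp = csd_trace(lfp + noise[, 2], rate_hz = s$rate_hz,
                           t0_s = s$t0_s, unit = "mV"),
       stim_times = stim_times,
       truth = list(scenario = s, stim_scale = scale))
}

#' Simulate an electrode calibration table
#'
#' The canonical standards are the six solutions used for in vivo K+
#' electrode calibration: 3.5, 4.5, 10, 20, 50 and 100 mM.
#'
#' @param concs_mM Standard concentrations (all > 0).
#' @param slope_mV_per_decade,offset_mV True Nernstian response.
#' @param noise_sd_mV Measurement noise SD (mV).
#' @param seed Integer RNG seed.
#' @return `data.frame` with columns `conc_mM`, `voltage_mV`.
#' @export
simulate_calibration <- function(concs_mM = c(3.5, 4.5, 10, 20, 50, 100),
                                 slope_mV_per_decade = 58, offset_mV = 0,
                                 noise_sd_mV = 0, seed = 1L) {
  if (any(concs_mM <= 0)) stop("concentrations must be positive")
  v <- offset_mV + slope_mV_per_decade * log10(concs_mM)
  if (noise_sd_mV > 0)
    v <- v + with_seed(seed, stats::rnorm(length(concs_mM), 0, noise_sd_mV))
  data.frame(conc_mM = concs_mM, voltage_mV = v)
}
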
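#' Widefield CSD scenario
#'
#' Ground-truth parameter bundle for a synthetic transcranial movie. The
#' defaults reproduce the regime of KCl-induced CSD experiments in
#' urethane-anesthetized G-CaMP7 mice: a 12.8 mm field imaged on a 64x64
#' binned grid at 10 Hz; KCl applied at t = 0 over the posterior (visual)
#' cortex for 10 min; waves propagating at 4.4 mm/min with ~200% ΔF/F peaks
#' lasting ~50 s above half-maximum; a 0.5-2 Hz slow-wave (UP/DOWN state)
#' baseline oscillation of ~3% RMS that is suppressed by each wave's local
#' passage and recovers exponentially; a post-CSD baseline step drop that
#' relaxes on the same time scale; additive Gaussian pixel noise.
#'
#' @param field_mm Side length of the imaged field (mm).
#' @param grid Pixels per side.
#' @param rate_hz Frame rate (Hz).
#' @param duration_s Recording length (s), starting at `t0_s`.
#' @param t0_s Start of the recording relative to KCl application (s);
#'   negative so a pre-KCl baseline exists.
#' @param kcl_window [time_window()] of KCl exposure.
#' @param origin_px Wave origin `c(row, col)` (KCl application site).
#' @param wave_onsets_s Sorted wave initiation times at the origin (s).
#' @param speed_mm_per_min Propagation speed.
#' @param wave_peak_dff Peak ΔF/F of the wave pulse (2.0 = 200%).
#' @param wave_duration_s Supra-half-maximum duration of the pulse at each
#'   pixel (s); must exceed the 2-s rise.
#' @param slowwave_freq_hz Slow-wave frequency (Hz).
#' @param slowwave_rms_dff RMS amplitude of the slow-wave in ΔF/F units
#'   (0.03 = 3%).
#' @param suppression_recovery_s Exponential time constant of slow-wave
#'   recovery (and baseline-drop relaxation) after local wave passage (s).
#' @param post_csd_baseline_drop_frac Fractional baseline step drop after
#'   passage, in [0, 1).
#' @param noise_sd_dff Gaussian pixel noise SD (ΔF/F units).
#' @param geometry `"radial"` (concentric from the origin) or `"planar"`
#'   (front parallel to image rows, distance measured along rows) wavefront.
#' @param truncate_ok Allow waves still in progress at the end of the movie.
#' @param seed Integer RNG seed.
#' @return An object of class `widefield_scenario`.
#' @export
widefield_scenario <- function(field_mm = 12.8, grid = 64L, rate_hz = 10,
                               duration_s = 900, t0_s = -120,
                               kcl_window = time_window(0, 600),
                               origin_px = c(round(0.85 * grid), round(0.5 * grid)),
                               wave_onsets_s = c(60, 341.1),
                               speed_mm_per_min = 4.4,
                               wave_peak_dff = 2.0,
                               wave_duration_s = 50,
                               slowwave_freq_hz = 1,
                               slowwave_rms_dff = 0.03,
                               suppression_recovery_s = 900,
                               post_csd_baseline_drop_frac = 0.1,
                               noise_sd_dff = 0.01,
                               geometry = c("radial", "planar"),
                               truncate_ok = FALSE,
                               seed = 1L) {
  geometry <- match.arg(geometry)
  if (is.unsorted(wave_onsets_s, strictly = TRUE) && length(wave_onsets_s) > 1)
    stop("wave_onsets_s must be sorted ascending")
  if (speed_mm_per_min <= 0) stop("speed must be > 0")
  if (grid < 1) stop("grid must be positive")
  if (post_csd_baseline_drop_frac < 0 || post_csd_baseline_drop_frac >= 1)
    stop("post_csd_baseline_drop_frac must be in [0, 1)")
  if (wave_duration_s <= 2) stop("wave_duration_s must exceed the 2-s rise")
  structure(list(field_mm = field_mm, grid = as.integer(grid), rate_hz = rate_hz,
                 duration_s = duration_s, t0_s = t0_s, kcl_window = kcl_window,
                 origin_px = origin_px, wave_onsets_s = wave_onsets_s,
                 speed_mm_per_min = speed_mm_per_min, wave_peak_dff = wave_peak_dff,
                 wave_duration_s = wave_duration_s,
                 slowwave_freq_hz = slowwave_freq_hz,
                 slowwave_rms_dff = slowwave_rms_dff,
                 suppression_recovery_s = suppression_recovery_s,
                 post_csd_baseline_drop_frac = post_csd_baseline_drop_frac,
                 noise_sd_dff = noise_sd_dff, geometry = geometry,
                 truncate_ok = truncate_ok, seed = as.integer(seed)),
            class = "widefield_scenario")
}

# distance (mm) of every pixel from the wave origin under the scenario geometry
scenario_distance_mm <- function(s) {
  pitch <- s$field_mm / s$grid
  rows <- seq_len(s$grid)
  cols <- seq_len(s$grid)
  if (s$geometry == "planar") {
    matrix(abs(rows - s$origin_px[1]) * pitch, s$grid, s$grid)
  } else {
    outer(rows, cols, function(r, c)
      sqrt((r - s$origin_px[1])^2 + (c - s$origin_px[2])^2) * pitch)
  }
}

#' Ground-truth wavefront arrival time at a pixel
#'
#' Time at which the rising front of wave `wave` reaches pixel
#' `(row, col)`: onset + distance / speed. The half-maximum crossing of the
#' trapezoid pulse follows 1 s later (half of the 2-s linear rise).
#'
#' @param s A `widefield_scenario`.
#' @param row,col Pixel coordinates (1-based).
#' @param wave Wave index.
#' @return Front arrival time (s).
#' @export
wavefront_arrival <- function(s, row, col, wave = 1L) {
  stopifnot(inherits(s, "widefield_scenario"))
  d <- scenario_distance_mm(s)[row, col]
  s$wave_onsets_s[wave] + d / (s$speed_mm_per_min / 60)
}

#' Simulate a widefield CSD movie
#'
#' Renders the scenario into a ΔF/F-scale movie (baseline level 1.0): the
#' baseline, multiplied by `(1 + slow-wave)`, carries a step drop after each
#' wave's local passage; the slow-wave amplitude is gated off at passage and
#' recovers exponentially; each wave is a radially (or planar) expanding
#' trapezoid pulse that rises linearly over 2 s to `wave_peak_dff`, holds,
#' and falls over 2 s so the supra-half-maximum duration at every pixel
#' equals `wave_duration_s`.
#'
#' @param s A [widefield_scenario()].
#' @return A list with `movie` (a `csd_movie`) and `truth`: per-wave,
#'   per-probe ground-truth front arrival, half-maximum arrival and passage
#'   times at the speed-estimation ROI centers (see [speed_rois()]), plus
#'   the true speed.
#' @export
simulate_widefield <- function(s) {
  stopifnot(inherits(s, "widefield_scenario"))
  v_mm_s <- s$speed_mm_per_min / 60
  nf <- round(s$duration_s * s$rate_hz)
  tt <- s$t0_s + (seq_len(nf) - 1) / s$rate_hz
  t_end <- s$t0_s + s$duration_s
  D <- scenario_distance_mm(s)
  h <- s$wave_duration_s - 2
  tau <- s$suppression_recovery_s
  npx <- s$grid^2
  dvec <- as.vector(D)

  for (w in seq_along(s$wave_onsets_s)) {
    wave_end <- s$wave_onsets_s[w] + max(dvec) / v_mm_s + 4 + h
    if (wave_end > t_end && !s$truncate_ok)
      stop(sprintf("wave %d extends beyond the movie end (%.1f > %.1f s); set truncate_ok",
                   w, wave_end, t_end))
  }

  pulses <- matrix(0, nf, npx)
  E <- matrix(0, nf, npx)  # exp(-(t - last passage)/tau); 0 before any passage
  for (w in seq_along(s$wave_onsets_s)) {
    a <- s$wave_onsets_s[w] + dvec / v_mm_s        # front arrival per pixel
    rel <- outer(tt, a, "-")
    p <- matrix(0, nf, npx)
    rise <- rel >= 0 & rel < 2
    hold <- rel >= 2 & rel < 2 + h
    fall <- rel >= 2 + h & rel < 4 + h
    p[rise] <- s$wave_peak_dff * rel[rise] / 2
    p[hold] <- s$wave_peak_dff
    p[fall] <- s$wave_peak_dff * (1 - (rel[fall] - 2 - h) / 2)
    pulses <- pulses + p
    since_pass <- rel - (1 + s$wave_duration_s)    # time since half-max passage
    passed <- since_pass >= 0
    E[passed] <- exp(-since_pass[passed] / tau)
  }
  base <- 1 - s$post_csd_baseline_drop_frac * E
  gate <- 1 - E
  slow <- sqrt(2) * s$slowwave_rms_dff * sin(2 * pi * s$slowwave_freq_hz * tt)
  sig <- base * (1 + slow * gate) + pulses
  if (s$noise_sd_dff > 0)
    sig <- sig + with_seed(s$seed, matrix(stats::rnorm(nf * npx, 0, s$noise_sd_dff), nf, npx))

  movie <- csd_movie(array(sig, c(nf, s$grid, s$grid)),
                     frame_rate_hz = s$rate_hz,
                     pixel_pitch_mm = s$field_mm / s$grid, t0_s = s$t0_s)

  rois <- tryCatch(speed_rois(s), error = function(e) NULL)
  if (is.null(rois))
    return(list(movie = movie,
                truth = list(speed_mm_per_min = s$speed_mm_per_min,
                             wave_onsets_s = s$wave_onsets_s,
                             separation_mm = NA_real_, rois = NULL,
                             scenario = s)))
  truth_rows <- do.call(rbind, lapply(seq_along(s$wave_onsets_s), function(w) {
    do.call(rbind, lapply(c("near", "far"), function(nm) {
      r <- rois[[nm]]
      cr <- r$rows[(length(r$rows) + 1) %/% 2]
      cc <- r$cols[(length(r$cols) + 1) %/% 2]
      fa <- wavefront_arrival(s, cr, cc, w)
      data.frame(wave = w, roi = nm, center_row = cr, center_col = cc,
                 front_arrival_s = fa, halfmax_arrival_s = fa + 1,
                 passage_s = fa + 1 + s$wave_duration_s)
    }))
  }))
  list(movie = movie,
       truth = list(speed_mm_per_min = s$speed_mm_per_min,
                    wave_onsets_s = s$wave_onsets_s,
                    separation_mm = rois$separation_mm,
                    rois = truth_rows,
                    scenario = s))
}

#' Standard speed-estimation ROI pair for a scenario
#'
#' A near ROI centered `near_offset_mm` anterior (toward lower row indices)
#' of the KCl origin and a far ROI a further `separation_mm` anterior, each
#' `size_px` x `size_px` pixels. Offsets are rounded to whole pixels; the
#' realized separation is returned and should be passed to [wave_speed()].
#'
#' @param s A `widefield_scenario`.
#' @param near_offset_mm Distance from origin to the near ROI center (mm).
#' @param separation_mm Nominal near-to-far center separation (mm).
#' @param size_px ROI side length in pixels (odd recommended).
#' @return List with `near`, `far` ([pixel_rect()]) and the realized
#'   `separation_mm`.
#' @export
speed_rois <- function(s, near_offset_mm = 0.5, separation_mm = 2.0, size_px = 5L) {
  pitch <- s$field_mm / s$grid
  near_row <- s$origin_px[1] - round(near_offset_mm / pitch)
  sep_px <- round(separation_mm / pitch)
  far_row <- near_row - sep_px
  half <- size_px %/% 2
  col0 <- s$origin_px[2] - half
  if (far_row - half < 1) stop("far ROI outside the field; reduce offsets")
  list(near = pixel_rect(near_row - half, col0, size_px, size_px),
       far = pixel_rect(far_row - half, col0, size_px, size_px),
       separation_mm = sep_px * pitch)
}
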
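#' Two-photon astrocyte scenario
#'
#' Ground truth for a synthetic cellular-resolution movie: circular
#' astrocyte somata whose post-CSD calcium event trains share a common
#' component so that the expected pairwise Pearson correlation equals
#' `pairwise_rho` exactly, plus gliopil patches with independent event
#' trains, on a noisy fluorescence baseline. Defaults emulate 30-Hz
#' two-photon recordings in which aberrant astrocytic activity appears
#' 15-300 s after the first CSD wave passage: somata are silent in the
#' pre-CSD window and active in the post-CSD window; gliopil patches emit
#' events throughout (the analysis selects gliopil ROIs from events in
#' pre/inter-wave reference periods, so those periods must contain events).
#'
#' @param grid Pixels per side.
#' @param rate_hz Frame rate (Hz).
#' @param duration_s Recording length (s).
#' @param n_somata Number of somata.
#' @param soma_radius_px Soma disk radius (px).
#' @param pre_csd_window,post_csd_window [time_window()]s; soma events exist
#'   only inside `post_csd_window`.
#' @param soma_event_rate_hz Poisson event rate per soma in the post window.
#' @param event_amp_dff Scale of the (unit-variance) soma signal in ΔF/F.
#' @param event_decay_s Exponential decay of the calcium transient (s).
#' @param pairwise_rho Target pairwise correlation in [0, 1].
#' @param gliopil_event_rate_hz Poisson event rate per gliopil patch.
#' @param gliopil_event_amp_dff Peak ΔF/F of a single gliopil event
#'   (process transients are large relative to the pixel noise, which is
#'   what makes the event-based gliopil ROI selection work).
#' @param n_gliopil_patches,gliopil_radius_px Gliopil patch count and radius.
#' @param baseline_f Baseline fluorescence level (arbitrary units).
#' @param noise_sd_dff Gaussian pixel noise SD in ΔF/F units.
#' @param seed Integer RNG seed.
#' @return An object of class `twophoton_scenario`.
#' @export
twophoton_scenario <- function(grid = 64L, rate_hz = 30, duration_s = 360,
                               n_somata = 20L, soma_radius_px = 3L,
                               pre_csd_window = time_window(0, 60),
                               post_csd_window = time_window(75, 360),
                               soma_event_rate_hz = 0.2,
                               event_amp_dff = 0.5, event_decay_s = 1.5,
                               pairwise_rho = 0.55,
                               gliopil_event_rate_hz = 0.05,
                               gliopil_event_amp_dff = 2.0,
                               n_gliopil_patches = 12L, gliopil_radius_px = 2L,
                               baseline_f = 100, noise_sd_dff = 0.35,
                               seed = 1L) {
  if (pairwise_rho < 0 || pairwise_rho > 1) stop("pairwise_rho must be in [0, 1]")
  structure(list(grid = as.integer(grid), rate_hz = rate_hz,
                 duration_s = duration_s, n_somata = as.integer(n_somata),
                 soma_radius_px = as.integer(soma_radius_px),
                 pre_csd_window = pre_csd_window,
                 post_csd_window = post_csd_window,
                 soma_event_rate_hz = soma_event_rate_hz,
                 event_amp_dff = event_amp_dff, event_decay_s = event_decay_s,
                 pairwise_rho = pairwise_rho,
                 gliopil_event_rate_hz = gliopil_event_rate_hz,
                 gliopil_event_amp_dff = gliopil_event_amp_dff,
                 n_gliopil_patches = as.integer(n_gliopil_patches),
                 gliopil_radius_px = as.integer(gliopil_radius_px),
                 baseline_f = baseline_f, noise_sd_dff = noise_sd_dff,
                 seed = as.integer(seed)),
            class = "twophoton_scenario")
}

# Poisson event train convolved with an exponential decay kernel, on the
# frame grid; returns the (unstandardized) signal and the event times
filtered_event_process <- function(nf, rate_hz, event_rate_hz, win_idx, decay_s) {
  sig <- numeric(nf)
  n_ev <- stats::rpois(1, event_rate_hz * length(win_idx) / rate_hz)
  ev_idx <- if (n_ev > 0) sort(sample(win_idx, n_ev, replace = TRUE)) else integer(0)
  if (n_ev > 0) {
    kern <- exp(-(0:ceiling(8 * decay_s * rate_hz)) / (decay_s * rate_hz))
    for (i in ev_idx) {
      j <- i:min(nf, i + length(kern) - 1L)
      sig[j] <- sig[j] + kern[seq_along(j)]
    }
  }
  list(signal = sig, event_idx = ev_idx)
}

# scale to unit SD over the given samples (left untouched if constant)
unit_sd <- function(x, idx) {
  s <- stats::sd(x[idx])
  if (is.na(s) || s == 0) x else x / s
}

disk_pixels <- function(center, radius, grid) {
  r0 <- max(1, center[1] - radius); r1 <- min(grid, center[1] + radius)
  c0 <- max(1, center[2] - radius); c1 <- min(grid, center[2] + radius)
  px <- expand.grid(row = r0:r1, col = c0:c1)
  px <- px[(px$row - center[1])^2 + (px$col - center[2])^2 <= radius^2, ]
  (px$col - 1L) * grid + px$row  # linear (column-major) frame indices
}

#' Simulate a two-photon astrocyte movie
#'
#' Soma i receives the ΔF/F signal
#' `amp * (sqrt(rho) * s(t) + sqrt(1 - rho) * n_i(t))` where `s` and the
#' `n_i` are independent unit-variance filtered Poisson event processes
#' confined to the post-CSD window, so the expected pairwise Pearson
#' correlation between soma traces equals `rho` by construction. Gliopil
#' patches carry independent event trains over the whole recording. The
#' rendered movie is `baseline_f * (1 + dff + noise)`.
#'
#' @param s A [twophoton_scenario()].
#' @return List with `movie` (a `csd_movie`), `mask` (integer matrix, 0 =
#'   background, k = soma k), and `truth` (soma centers/pixels, gliopil
#'   pixels, per-soma and shared event frame indices, target rho, scenario).
#' @export
simulate_twophoton <- function(s) {
  stopifnot(inherits(s, "twophoton_scenario"))
  nf <- round(s$duration_s * s$rate_hz)
  tt <- (seq_len(nf) - 1) / s$rate_hz
  npx <- s$grid^2
  with_seed(s$seed, {
    # non-overlapping soma placement with bounded retries
    min_gap <- 2 * s$soma_radius_px + 2
    centers <- matrix(NA_integer_, 0, 2)
    tries <- 0L
    while (nrow(centers) < s$n_somata) {
      tries <- tries + 1L
      if (tries > 500L * s$n_somata)
        stop("could not place non-overlapping somata; reduce n_somata or radius")
      cand <- c(sample(seq(s$soma_radius_px + 1, s$grid - s$soma_radius_px), 1),
                sample(seq(s$soma_radius_px + 1, s$grid - s$soma_radius_px), 1))
      if (nrow(centers) == 0 ||
          all((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2 >= min_gap^2))
        centers <- rbind(centers, cand)
    }
    soma_px <- lapply(seq_len(s$n_somata), function(i)
      disk_pixels(centers[i, ], s$soma_radius_px, s$grid))
    mask <- matrix(0L, s$grid, s$grid)
    for (i in seq_along(soma_px)) mask[soma_px[[i]]] <- i

    post_idx <- which(tt >= s$post_csd_window$start_s & tt < s$post_csd_window$end_s)
    shared <- filtered_event_process(nf, s$rate_hz, s$soma_event_rate_hz,
                                     post_idx, s$event_decay_s)
    sh <- unit_sd(shared$signal, post_idx)
    soma_events <- vector("list", s$n_somata)
    dff <- matrix(0, nf, npx)
    for (i in seq_len(s$n_somata)) {
      own <- filtered_event_process(nf, s$rate_hz, s$soma_event_rate_hz,
                                    post_idx, s$event_decay_s)
      soma_events[[i]] <- own$event_idx
      x <- s$event_amp_dff * (sqrt(s$pairwise_rho) * sh +
                              sqrt(1 - s$pairwise_rho) * unit_sd(own$signal, post_idx))
      dff[, soma_px[[i]]] <- x
    }

    # gliopil patches on non-soma pixels, events over the whole recording
    taken <- which(mask > 0)
    glio_patch_px <- vector("list", s$n_gliopil_patches)
    glio_events <- vector("list", s$n_gliopil_patches)
    for (g in seq_len(s$n_gliopil_patches)) {
      for (k in 1:200) {
        cand <- c(sample(seq(s$gliopil_radius_px + 1, s$grid - s$gliopil_radius_px), 1),
                  sample(seq(s$gliopil_radius_px + 1, s$grid - s$gliopil_radius_px), 1))
        px <- disk_pixels(cand, s$gliopil_radius_px, s$grid)
        if (!any(px %in% taken)) break
        px <- integer(0)
      }
      if (length(px) == 0) next
      taken <- c(taken, px)
      glio_patch_px[[g]] <- px
      ev <- filtered_event_process(nf, s$rate_hz, s$gliopil_event_rate_hz,
                                   seq_len(nf), s$event_decay_s)
      glio_events[[g]] <- ev$event_idx
      # fixed event amplitude (kernel peaks at 1): a single transient rises
      # gliopil_event_amp_dff above baseline
      dff[, px] <- s$gliopil_event_amp_dff * ev$signal
    }

    raw <- s$baseline_f * (1 + dff)
    if (s$noise_sd_dff > 0)
      raw <- raw + s$baseline_f * matrix(stats::rnorm(nf * npx, 0, s$noise_sd_dff), nf, npx)
    movie <- csd_movie(array(raw, c(nf, s$grid, s$grid)),
                       frame_rate_hz = s$rate_hz, pixel_pitch_mm = 0.001, t0_s = 0)
    list(movie = movie, mask = mask,
         truth = list(soma_centers = centers, soma_pixels = soma_px,
                      gliopil_patch_pixels = glio_patch_px,
                      gliopil_pixels = sort(unique(unlist(glio_patch_px))),
                      soma_event_idx = soma_events,
                      shared_event_idx = shared$event_idx,
                      gliopil_event_idx = glio_events,
                      pairwise_rho = s$pairwise_rho, scenario = s))
  })
}
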
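#' Per-pixel ΔF/F for a two-photon movie
#'
#' Each pixel's baseline F is its temporal mean over the pre-CSD period;
#' the output is `(x - F) / F` per pixel. Pixels with `F <= 0` cannot be
#' normalized: they are set to `NA`, counted, and reported via the
#' `masked_pixels` attribute and a warning.
#'
#' @param m A `csd_movie`.
#' @param pre_period [time_window()] inside the movie defining the baseline.
#' @return A `csd_movie` of ΔF/F values with attribute `masked_pixels`
#'   (linear pixel indices with non-positive baseline).
#' @export
pixel_dff <- function(m, pre_period) {
  stopifnot(inherits(m, "csd_movie"), inherits(pre_period, "time_window"))
  tt <- movie_times(m)
  idx <- which(tt >= pre_period$start_s & tt < pre_period$end_s)
  if (length(idx) < 1) stop("pre_period contains no frames")
  d <- dim(m$data)
  mat <- matrix(m$data, nrow = d[1])          # [frame, pixel]
  f0 <- colMeans(mat[idx, , drop = FALSE])
  bad <- which(f0 <= 0)
  f0[bad] <- NA_real_
  dff <- sweep(sweep(mat, 2, f0, "-"), 2, f0, "/")
  if (length(bad))
    warning(sprintf("%d pixel(s) with baseline F <= 0 masked", length(bad)))
  out <- csd_movie(array(dff, d), frame_rate_hz = m$frame_rate_hz,
                   pixel_pitch_mm = m$pixel_pitch_mm, t0_s = m$t0_s)
  attr(out, "masked_pixels") <- bad
  out
}

#' Soma ROI set from a binary marker mask
#'
#' Automates soma selection from an astrocyte-marker (SR101) image:
#' connected components of the binary mask with area inside
#' `[min_px, max_px]` become soma ROIs; the non-soma region is the frame
#' minus the dilated somata. Touching somata merge into one component
#' (documented behavior of connectivity labelling).
#'
#' @param mask Binary/logical matrix with the movie's frame geometry.
#' @param min_px,max_px Accepted component area range (pixels).
#' @param dilate_px Dilation radius separating somata from the non-soma
#'   region (pixels).
#' @return An object of class `roi_set`: `soma_rois` (named list of linear
#'   pixel-index vectors), `nonsoma_roi`, `provenance = "mask-derived"`.
#'   Zero accepted components yield an empty set with a warning.
#' @export
soma_rois_from_mask <- function(mask, min_px = 5L, max_px = 1000L, dilate_px = 2L) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  lab <- EBImage::bwlabel(mask > 0)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_px & areas <= max_px)
  soma_rois <- lapply(keep, function(k) which(lab == k))
  names(soma_rois) <- if (length(keep)) sprintf("soma_%02d", seq_along(keep)) else character(0)
  if (length(soma_rois) == 0) warning("no soma components within the area range")
  soma_mask <- matrix(0, nrow(mask), ncol(mask))
  for (px in soma_rois) soma_mask[px] <- 1
  if (length(soma_rois) && dilate_px > 0) {
    brush <- EBImage::makeBrush(2L * dilate_px + 1L, shape = "disc")
    soma_mask <- EBImage::dilate(soma_mask, brush)
  }
  roi_set(soma_rois, nonsoma_roi = which(soma_mask == 0), provenance = "mask-derived")
}

#' Construct an ROI set
#'
#' @param soma_rois Named list of pairwise-disjoint linear pixel-index
#'   vectors, one per soma.
#' @param nonsoma_roi Linear pixel indices disjoint from all somata.
#' @param provenance One of `"manual"`, `"mask-derived"`, `"event-derived"`.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(soma_rois, nonsoma_roi,
                    provenance = c("manual", "mask-derived", "event-derived")) {
  provenance <- match.arg(provenance)
  all_soma <- unlist(soma_rois, use.names = FALSE)
  if (anyDuplicated(all_soma)) stop("soma ROIs must be pairwise disjoint")
  if (length(intersect(all_soma, nonsoma_roi)))
    stop("non-soma ROI must be disjoint from somata")
  structure(list(soma_rois = soma_rois, nonsoma_roi = nonsoma_roi,
                 provenance = provenance), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d somata (%s), non-soma ROI of %d px\n",
              length(x$soma_rois), x$provenance, length(x$nonsoma_roi)))
  invisible(x)
}

#' High-calcium exceedance mask for an ROI
#'
#' A pixel-frame is a high-Ca2+ event when its ΔF/F exceeds that pixel's
#' reference-window temporal mean + `k_sd` SD (default +4 SD). Statistics
#' are per pixel over `ref` frames. Zero-variance (or masked/NA) pixels are
#' excluded from the output and counted in the `excluded` attribute.
#'
#' @param dff A ΔF/F `csd_movie` from [pixel_dff()].
#' @param roi Linear pixel indices.
#' @param k_sd Threshold in SDs.
#' @param ref Reference [time_window()].
#' @return Logical matrix `[frame, pixel]` over all frames, with attributes
#'   `pixels` (the retained linear indices) and `excluded` (count).
#' @export
high_ca_mask <- function(dff, roi, k_sd = 4, ref) {
  stopifnot(inherits(dff, "csd_movie"), inherits(ref, "time_window"))
  if (length(roi) < 1) stop("empty ROI")
  tt <- movie_times(dff)
  ridx <- which(tt >= ref$start_s & tt < ref$end_s)
  if (length(ridx) < 2) stop("reference window must contain >= 2 frames")
  d <- dim(dff$data)
  mat <- matrix(dff$data, nrow = d[1])[, roi, drop = FALSE]
  mu <- colMeans(mat[ridx, , drop = FALSE])
  sdev <- apply(mat[ridx, , drop = FALSE], 2, stats::sd)
  ok <- is.finite(mu) & is.finite(sdev) & sdev > 0
  excluded <- sum(!ok)
  if (excluded) warning(sprintf("%d zero-variance or masked pixel(s) excluded", excluded))
  thr <- mu[ok] + k_sd * sdev[ok]
  out <- sweep(mat[, ok, drop = FALSE], 2, thr, ">")
  out[is.na(out)] <- FALSE
  attr(out, "pixels") <- roi[ok]
  attr(out, "excluded") <- excluded
  out
}

#' High-calcium event probability P(High Ca2+)
#'
#' The probability per pixel-frame of a supra-threshold (+4 SD) ΔF/F value
#' inside the evaluation window: total high-Ca2+ pixel count divided by the
#' ROI pixel count times the number of frames. Computed per soma, or pooled
#' over the entire non-soma ROI.
#'
#' @param dff A ΔF/F `csd_movie`.
#' @param rois A [roi_set()].
#' @param eval_window Evaluation [time_window()] (e.g. 15-300 s after the
#'   first wave passage for post-CSD statistics).
#' @param mode `"per_soma"` or `"pooled_nonsoma"`.
#' @param k_sd Threshold in SDs.
#' @param ref Reference [time_window()] for the threshold statistics
#'   (pre-CSD by default choice of the caller).
#' @return `data.frame` with `roi_id`, `p_high`, `n_high`, `n_pixels`,
#'   `n_frames`.
#' @export
event_probability <- function(dff, rois, eval_window,
                              mode = c("per_soma", "pooled_nonsoma"),
                              k_sd = 4, ref) {
  mode <- match.arg(mode)
  stopifnot(inherits(rois, "roi_set"), inherits(eval_window, "time_window"))
  tt <- movie_times(dff)
  eidx <- which(tt >= eval_window$start_s & tt < eval_window$end_s)
  if (length(eidx) < 1) stop("evaluation window contains no frames")
  one <- function(px, id) {
    hm <- high_ca_mask(dff, px, k_sd = k_sd, ref = ref)
    sub <- hm[eidx, , drop = FALSE]
    n_px <- ncol(sub)
    if (n_px == 0) stop("empty ROI after exclusions: ", id)
    data.frame(roi_id = id, p_high = sum(sub) / (n_px * length(eidx)),
               n_high = sum(sub), n_pixels = n_px, n_frames = length(eidx))
  }
  if (mode == "per_soma") {
    if (length(rois$soma_rois) == 0) stop("no soma ROIs")
    do.call(rbind, Map(one, rois$soma_rois, names(rois$soma_rois)))
  } else {
    one(rois$nonsoma_roi, "nonsoma")
  }
}

#' Gliopil ROI from reference-period events
#'
#' Selects the non-soma pixels that show at least one high-Ca2+ event
#' (same +4 SD rule as scoring) during any of the reference periods —
#' pre-CSD or inter-wave intervals. An empty result warns and falls back
#' to the whole non-soma region (flagged by the `fallback` attribute).
#'
#' @param dff A ΔF/F `csd_movie`.
#' @param ref_periods List of [time_window()]s.
#' @param nonsoma_roi Linear pixel indices of the candidate non-soma region.
#' @param k_sd Threshold in SDs.
#' @return Sorted linear pixel indices with attribute `fallback`.
#' @export
gliopil_roi_from_events <- function(dff, ref_periods, nonsoma_roi, k_sd = 4) {
  if (inherits(ref_periods, "time_window")) ref_periods <- list(ref_periods)
  tt <- movie_times(dff)
  hit <- logical(length(nonsoma_roi))
  for (w in ref_periods) {
    hm <- high_ca_mask(dff, nonsoma_roi, k_sd = k_sd, ref = w)
    widx <- which(tt >= w$start_s & tt < w$end_s)
    hits <- colSums(hm[widx, , drop = FALSE]) > 0
    hit[match(attr(hm, "pixels"), nonsoma_roi)] <- hit[match(attr(hm, "pixels"), nonsoma_roi)] | hits
  }
  out <- sort(nonsoma_roi[hit])
  fallback <- length(out) == 0
  if (fallback) {
    warning("no reference-period events; falling back to the whole non-soma region")
    out <- sort(nonsoma_roi)
  }
  attr(out, "fallback") <- fallback
  out
}

#' Mean ΔF/F traces of soma ROIs
#'
#' The soma trace is the mean ΔF/F over the soma's pixels per frame —
#' the signal entering pairwise correlation analysis.
#'
#' @param dff A ΔF/F `csd_movie`.
#' @param rois A [roi_set()] (or named list of pixel-index vectors).
#' @param window Optional [time_window()] restriction.
#' @return Numeric matrix `[frame, soma]`.
#' @export
soma_traces <- function(dff, rois, window = NULL) {
  stopifnot(inherits(dff, "csd_movie"))
  soma <- if (inherits(rois, "roi_set")) rois$soma_rois else rois
  d <- dim(dff$data)
  mat <- matrix(dff$data, nrow = d[1])
  keep <- seq_len(d[1])
  if (!is.null(window)) {
    tt <- movie_times(dff)
    keep <- which(tt >= window$start_s & tt < window$end_s)
  }
  out <- vapply(soma, function(px)
    rowMeans(mat[keep, px, drop = FALSE]), numeric(length(keep)))
  colnames(out) <- names(soma)
  out
}

#' Pairwise correlation of soma calcium traces
#'
#' Pearson correlation for each unordered soma pair;
#' `"mean_per_recording"` averages the upper triangle — the per-mouse
#' statistic used to compare post-CSD desynchronization against the awake
#' state. Zero-variance traces are excluded with a warning.
#'
#' @param traces Numeric matrix `[time, cell]` (e.g. from [soma_traces()])
#'   or list of equal-length numeric vectors / `csd_trace`s.
#' @param aggregate `"per_pair"` (full correlation matrix) or
#'   `"mean_per_recording"` (scalar mean of the upper triangle).
#' @return Correlation matrix or scalar.
#' @export
pairwise_soma_correlation <- function(traces,
                                      aggregate = c("per_pair", "mean_per_recording")) {
  aggregate <- match.arg(aggregate)
  if (is.list(traces)) {
    traces <- vapply(traces, function(x) {
      if (inherits(x, "csd_trace")) x$values else as.numeric(x)
    }, numeric(length(if (inherits(traces[[1]], "csd_trace")) traces[[1]]$values else traces[[1]])))
  }
  if (ncol(traces) < 2) stop("need at least 2 traces")
  v <- apply(traces, 2, stats::var)
  if (any(v == 0)) {
    warning(sprintf("%d zero-variance trace(s) excluded", sum(v == 0)))
    traces <- traces[, v > 0, drop = FALSE]
    if (ncol(traces) < 2) stop("fewer than 2 traces with nonzero variance")
  }
  cm <- stats::cor(traces)
  if (aggregate == "per_pair") cm else mean(cm[upper.tri(cm)])
}
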
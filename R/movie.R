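#' Construct a movie
#'
#' Container for an imaging stack: a 3-D array indexed `[frame, row, col]`
#' plus acquisition geometry. Widefield acquisitions are nominally 512x512
#' 16-bit at 10 Hz; two-photon stacks run at 30 Hz.
#'
#' @param data 3-D numeric array `[frame, row, col]` with at least one frame.
#' @param frame_rate_hz Frame rate in Hz (> 0).
#' @param pixel_pitch_mm Physical size of one pixel in mm (> 0).
#' @param t0_s Time of the first frame on the experiment clock (s).
#' @return An object of class `csd_movie`.
#' @export
csd_movie <- function(data, frame_rate_hz, pixel_pitch_mm, t0_s = 0) {
  if (length(dim(data)) != 3L) stop("data must be a 3-D array [frame, row, col]")
  if (dim(data)[1] < 1L) stop("movie must have at least one frame")
  if (!is.finite(frame_rate_hz) || frame_rate_hz <= 0) stop("frame_rate_hz must be > 0")
  if (!is.finite(pixel_pitch_mm) || pixel_pitch_mm <= 0) stop("pixel_pitch_mm must be > 0")
  structure(list(data = data, frame_rate_hz = frame_rate_hz,
                 pixel_pitch_mm = pixel_pitch_mm, t0_s = t0_s),
            class = "csd_movie")
}

#' @export
print.csd_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<csd_movie> %d frames of %dx%d @ %g Hz, pitch %g mm, t0 = %g s\n",
              d[1], d[2], d[3], x$frame_rate_hz, x$pixel_pitch_mm, x$t0_s))
  invisible(x)
}

#' Frame times of a movie
#' @param m A `csd_movie`.
#' @return Numeric vector of frame times (s).
#' @export
movie_times <- function(m) {
  stopifnot(inherits(m, "csd_movie"))
  m$t0_s + (seq_len(dim(m$data)[1]) - 1) / m$frame_rate_hz
}

#' Read a multi-page TIFF movie
#'
#' Metadata (frame rate, pixel pitch, start time) comes from a YAML sidecar
#' or from the explicit arguments; arguments override the sidecar. A missing
#' frame rate or pixel pitch is an error, never defaulted.
#'
#' @param path Multi-page TIFF path.
#' @param meta Optional YAML sidecar path with fields `frame_rate_hz`,
#'   `pixel_pitch_mm`, `t0_s`.
#' @param frame_rate_hz,pixel_pitch_mm,t0_s Optional metadata overrides.
#' @return A `csd_movie` with frame order intact and intensities unmodified
#'   (16-bit pages are returned as integers 0..65535).
#' @export
read_movie <- function(path, meta = NULL, frame_rate_hz = NULL,
                       pixel_pitch_mm = NULL, t0_s = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent geometry: TIFF pages have differing shapes")
  md <- list()
  if (!is.null(meta)) {
    if (!file.exists(meta)) stop("sidecar not found: ", meta)
    md <- yaml::read_yaml(meta)
  }
  rate <- if (!is.null(frame_rate_hz)) frame_rate_hz else md$frame_rate_hz
  pitch <- if (!is.null(pixel_pitch_mm)) pixel_pitch_mm else md$pixel_pitch_mm
  t0 <- if (!is.null(t0_s)) t0_s else if (!is.null(md$t0_s)) md$t0_s else 0
  if (is.null(rate)) stop("frame_rate_hz missing: provide a sidecar or argument")
  if (is.null(pitch)) stop("pixel_pitch_mm missing: provide a sidecar or argument")
  arr <- array(0, c(length(pages), dims[1, 1], dims[2, 1]))
  for (k in seq_along(pages)) arr[k, , ] <- pages[[k]]
  csd_movie(arr, frame_rate_hz = rate, pixel_pitch_mm = pitch, t0_s = t0)
}

#' Write a movie to multi-page TIFF with a YAML sidecar
#'
#' 16-bit storage requires integer intensities in 0..65535 and round-trips
#' bit-exactly through [read_movie()].
#'
#' @param m A `csd_movie` with integer-valued data in 0..65535.
#' @param path Output TIFF path.
#' @param meta Output YAML sidecar path (default `<path>.yaml`).
#' @return `path`, invisibly.
#' @export
write_movie <- function(m, path, meta = paste0(path, ".yaml")) {
  stopifnot(inherits(m, "csd_movie"))
  d <- m$data
  if (any(d < 0 | d > 65535) || any(d != round(d)))
    stop("16-bit TIFF storage requires integer intensities in 0..65535")
  pages <- lapply(seq_len(dim(d)[1]), function(k) d[k, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  yaml::write_yaml(list(frame_rate_hz = m$frame_rate_hz,
                        pixel_pitch_mm = m$pixel_pitch_mm,
                        t0_s = m$t0_s), meta)
  invisible(path)
}

#' Spatially bin a movie by block averaging
#'
#' Each output pixel is the mean of its `factor` x `factor` input block
#' (e.g. 512x512 reduced to 64x64 with `factor = 8`); the pixel pitch is
#' scaled accordingly. Block means keep the per-frame global mean intensity
#' unchanged, and downstream ΔF/F is invariant to the choice of mean over
#' sum.
#'
#' @param m A `csd_movie` whose rows and cols are divisible by `factor`.
#' @param factor Positive integer binning factor.
#' @return The binned `csd_movie`.
#' @export
bin_movie <- function(m, factor) {
  stopifnot(inherits(m, "csd_movie"))
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be a positive integer")
  d <- dim(m$data)
  if (d[2] %% factor != 0L || d[3] %% factor != 0L)
    stop(sprintf("movie geometry %dx%d not divisible by factor %d", d[2], d[3], factor))
  nr <- d[2] %/% factor
  nc <- d[3] %/% factor
  # reshape so that the factor x factor block dimensions lead, then colMeans
  a <- array(m$data, c(d[1], factor, nr, factor, nc))
  a <- aperm(a, c(2, 4, 1, 3, 5))
  out <- array(colMeans(matrix(a, nrow = factor * factor)), c(d[1], nr, nc))
  csd_movie(out, frame_rate_hz = m$frame_rate_hz,
            pixel_pitch_mm = m$pixel_pitch_mm * factor, t0_s = m$t0_s)
}

#' Axis-aligned rectangular pixel ROI
#'
#' Indices are 1-based and inclusive, matching R array indexing.
#'
#' @param row,col Top-left corner (1-based).
#' @param nrow,ncol Extent in pixels (>= 1).
#' @return An object of class `pixel_rect`.
#' @export
pixel_rect <- function(row, col, nrow = 1L, ncol = 1L) {
  if (nrow < 1L || ncol < 1L) stop("ROI must contain at least one pixel")
  if (row < 1L || col < 1L) stop("ROI indices are 1-based")
  structure(list(rows = seq.int(row, row + nrow - 1L),
                 cols = seq.int(col, col + ncol - 1L)),
            class = "pixel_rect")
}

#' Extract the mean trace of a rectangular ROI
#'
#' @param m A `csd_movie`.
#' @param roi A [pixel_rect()] within the movie bounds.
#' @return A `csd_trace` (unit `au`) of per-frame ROI means; rate and start
#'   time are inherited from the movie.
#' @export
extract_roi_trace <- function(m, roi) {
  stopifnot(inherits(m, "csd_movie"), inherits(roi, "pixel_rect"))
  d <- dim(m$data)
  if (max(roi$rows) > d[2] || max(roi$cols) > d[3])
    stop("ROI out of movie bounds")
  sub <- m$data[, roi$rows, roi$cols, drop = FALSE]
  vals <- rowMeans(matrix(sub, nrow = d[1]))
  csd_trace(vals, rate_hz = m$frame_rate_hz, t0_s = m$t0_s, unit = "au")
}
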
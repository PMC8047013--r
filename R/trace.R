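#' Construct a time-series trace
#'
#' The universal 1-D signal container of the package: a uniformly sampled
#' series with a sampling rate, a start time on the experiment clock
#' (t = 0 at KCl application by convention) and a unit tag.
#'
#' @param values Numeric vector of samples. Must not contain NA/NaN.
#' @param rate_hz Sampling rate in Hz (> 0).
#' @param t0_s Time of the first sample in seconds on the experiment clock.
#' @param unit One of `"au"` (raw fluorescence), `"dff"` (ΔF/F), `"mV"`, `"mM"`.
#' @return An object of class `csd_trace`.
#' @examples
#' tr <- csd_trace(sin(seq(0, 2 * pi, length.out = 100)), rate_hz = 10)
#' trace_times(tr)[1:5]
#' @export
csd_trace <- function(values, rate_hz, t0_s = 0, unit = c("au", "dff", "mV", "mM")) {
  unit <- match.arg(unit)
  values <- as.numeric(values)
  if (length(values) < 1L) stop("trace must contain at least one sample")
  if (anyNA(values)) stop("trace values must not contain NA/NaN")
  if (!is.finite(rate_hz) || rate_hz <= 0) stop("rate_hz must be > 0")
  if (!is.finite(t0_s)) stop("t0_s must be finite")
  structure(list(values = values, rate_hz = rate_hz, t0_s = t0_s, unit = unit),
            class = "csd_trace")
}

#' Sample times of a trace
#'
#' @param t A `csd_trace`.
#' @return Numeric vector of sample times in seconds: `t0_s + (k - 1) / rate_hz`.
#' @export
trace_times <- function(t) {
  stopifnot(inherits(t, "csd_trace"))
  t$t0_s + (seq_along(t$values) - 1) / t$rate_hz
}

#' @export
length.csd_trace <- function(x) length(x$values)

#' @export
print.csd_trace <- function(x, ...) {
  cat(sprintf("<csd_trace> %d samples @ %g Hz, unit=%s, t=[%.3f, %.3f) s\n",
              length(x$values), x$rate_hz, x$unit,
              x$t0_s, x$t0_s + length(x$values) / x$rate_hz))
  invisible(x)
}

#' @export
plot.csd_trace <- function(x, ...) {
  graphics::plot(trace_times(x), x$values, type = "l",
                 xlab = "time (s)", ylab = x$unit, ...)
  invisible(x)
}

#' Half-open time window
#'
#' Windows are half-open `[start_s, end_s)`: a sample at exactly `end_s` is
#' excluded. Used for baseline periods, the KCl exposure window, and
#' evaluation epochs.
#'
#' @param start_s,end_s Window bounds in seconds; `end_s > start_s`.
#' @return An object of class `time_window`.
#' @export
time_window <- function(start_s, end_s) {
  if (!is.finite(start_s) || !is.numeric(end_s)) stop("window bounds must be numeric")
  if (!(end_s > start_s)) stop("end_s must be > start_s")
  structure(list(start_s = start_s, end_s = end_s), class = "time_window")
}

#' @export
print.time_window <- function(x, ...) {
  cat(sprintf("<time_window> [%g, %g) s\n", x$start_s, x$end_s))
  invisible(x)
}

#' Indices of trace samples falling in a half-open time window
#'
#' @param t A `csd_trace`.
#' @param win A `time_window`.
#' @return Integer vector of indices with `start_s <= time < end_s`.
#' @export
window_indices <- function(t, win) {
  stopifnot(inherits(t, "csd_trace"), inherits(win, "time_window"))
  tt <- trace_times(t)
  which(tt >= win$start_s & tt < win$end_s)
}

#' Write a trace to delimited text
#'
#' Stores unit, rate and start time in `#`-prefixed header lines followed by
#' `time_s,value` rows. Values are printed with 17 significant digits so the
#' write/read cycle is lossless for float64.
#'
#' @param t A `csd_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(t, path) {
  stopifnot(inherits(t, "csd_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# csd_trace v1",
               sprintf("# unit: %s", t$unit),
               sprintf("# rate_hz: %.17g", t$rate_hz),
               sprintf("# t0_s: %.17g", t$t0_s),
               "time_s,value"), con)
  tt <- trace_times(t)
  writeLines(sprintf("%.17g,%.17g", tt, t$values), con)
  invisible(path)
}

#' Read a trace written by [write_trace()]
#'
#' Missing unit or rate metadata in the header is an error: sampling-rate
#' guesses would corrupt every downstream timing estimate.
#'
#' @param path File path.
#' @return A `csd_trace`.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    m <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    if (length(m) != 1L) return(NULL)
    sub(sprintf("^# %s:\\s*", key), "", m)
  }
  unit <- get_meta("unit")
  rate <- get_meta("rate_hz")
  t0 <- get_meta("t0_s")
  if (is.null(unit) || is.null(rate))
    stop("trace header is missing unit or rate_hz metadata")
  body <- lines[!grepl("^#", lines)]
  if (length(body) < 2L || body[1] != "time_s,value")
    stop("malformed trace file: expected 'time_s,value' header")
  parts <- strsplit(body[-1], ",", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols != 2L)) stop("malformed trace file: expected 2 columns")
  vals <- as.numeric(vapply(parts, `[[`, "", 2L))
  if (anyNA(vals)) stop("malformed trace file: non-numeric values")
  csd_trace(vals, rate_hz = as.numeric(rate),
            t0_s = if (is.null(t0)) 0 else as.numeric(t0), unit = unit)
}
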
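#' Uniformly sampled voltage trace
#'
#' The basic container for continuous recordings: a numeric vector of
#' voltage samples together with its sampling rate and start time. All
#' filtering, correction and correlation operations in the package act on
#' these objects and return new ones; samples are always held in double
#' precision regardless of how they were stored on disk.
#'
#' @param samples Numeric vector of voltage values (conventionally microvolts).
#' @param fs_hz Sampling rate in Hz (single positive number).
#' @param t0_s Time of the first sample in seconds.
#' @param units Unit label carried along for display and sidecar metadata.
#'
#' @return An object of class `lfp_signal` with fields `samples`, `fs_hz`,
#'   `t0_s` and `units`.
#' @seealso [read_signal()], [write_signal()], [generate_pair()]
#' @export
#' @examples
#' s <- lfp_signal(sin(2 * pi * 2 * (0:999) / 1000), fs_hz = 1000)
#' signal_duration(s)
lfp_signal <- function(samples, fs_hz, t0_s = 0, units = "uV") {
  samples <- as.numeric(samples)
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || !is.finite(fs_hz) || fs_hz <= 0) {
    stop("`fs_hz` must be a single positive finite number", call. = FALSE)
  }
  if (length(samples) < 1L) {
    stop("a signal must contain at least one sample", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("signal samples must all be finite", call. = FALSE)
  }
  structure(
    list(samples = samples, fs_hz = fs_hz, t0_s = as.numeric(t0_s), units = units),
    class = "lfp_signal"
  )
}

#' Duration and time axis of a signal
#'
#' @param x An [lfp_signal()].
#' @return `signal_duration()` returns the record length in seconds
#'   (`n / fs`); `signal_times()` the per-sample time axis.
#' @export
signal_duration <- function(x) {
  stopifnot(inherits(x, "lfp_signal"))
  length(x$samples) / x$fs_hz
}

#' @rdname signal_duration
#' @export
signal_times <- function(x) {
  stopifnot(inherits(x, "lfp_signal"))
  x$t0_s + (seq_along(x$samples) - 1) / x$fs_hz
}

#' @export
print.lfp_signal <- function(x, ...) {
  cat(sprintf(
    "<lfp_signal> %d samples @ %g Hz (%.3f s), %s; sd = %.3g\n",
    length(x$samples), x$fs_hz, signal_duration(x), x$units,
    stats::sd(x$samples)
  ))
  invisible(x)
}

#' @export
plot.lfp_signal <- function(x, ...) {
  graphics::plot(signal_times(x), x$samples, type = "l",
                 xlab = "time (s)", ylab = x$units, ...)
  invisible(x)
}

#' Sorted spike (event) times
#'
#' Event times in seconds within a recording of known duration, as produced
#' by [derive_spikes()] or read from a plain-text spike file. Times must be
#' strictly increasing and contained in `[0, duration_s]`.
#'
#' @param times_s Numeric vector of event times (seconds), strictly increasing.
#' @param duration_s Span of the recording the events belong to.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times_s, duration_s) {
  times_s <- as.numeric(times_s)
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s <= 0) {
    stop("`duration_s` must be a single positive number", call. = FALSE)
  }
  if (length(times_s) > 0) {
    if (!all(is.finite(times_s))) stop("spike times must be finite", call. = FALSE)
    if (any(diff(times_s) <= 0)) {
      stop("spike times must be strictly increasing", call. = FALSE)
    }
    if (times_s[1] < 0 || times_s[length(times_s)] > duration_s) {
      stop("spike times must lie in [0, duration_s]", call. = FALSE)
    }
  }
  structure(list(times_s = times_s, duration_s = as.numeric(duration_s)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d events over %.3f s (rate %.3g Hz)\n",
              length(x$times_s), x$duration_s,
              length(x$times_s) / x$duration_s))
  invisible(x)
}

#' Read and write signal files
#'
#' Signals are stored as flat little-endian float32 binary with a JSON
#' sidecar (`<path>.json`) holding the sampling rate, units, start time and
#' sample count, so a trace can be exchanged with any language that can
#' read raw floats.
#'
#' @param x An [lfp_signal()].
#' @param path Path of the binary data file; the sidecar is written next to
#'   it at `<path>.json`.
#' @return `write_signal()` returns `path` invisibly; `read_signal()`
#'   returns an [lfp_signal()].
#' @export
write_signal <- function(x, path) {
  stopifnot(inherits(x, "lfp_signal"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(x$samples), con, size = 4L, endian = "little")
  meta <- list(fs_hz = x$fs_hz, units = x$units, n_samples = length(x$samples),
               t0_s = x$t0_s, dtype = "float32le")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_signal
#' @export
read_signal <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path)) stop("signal file not found: ", path, call. = FALSE)
  if (!file.exists(sidecar)) stop("missing JSON sidecar: ", sidecar, call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (field in c("fs_hz", "n_samples")) {
    if (is.null(meta[[field]])) {
      stop("sidecar is missing required field `", field, "`", call. = FALSE)
    }
  }
  con <- file(path, "rb")
  on.exit(close(con))
  samples <- readBin(con, what = "numeric", n = meta$n_samples, size = 4L,
                     endian = "little")
  if (length(samples) != meta$n_samples) {
    stop("signal file is truncated: expected ", meta$n_samples, " samples, got ",
         length(samples), call. = FALSE)
  }
  lfp_signal(samples, fs_hz = meta$fs_hz,
             t0_s = if (is.null(meta$t0_s)) 0 else meta$t0_s,
             units = if (is.null(meta$units)) "uV" else meta$units)
}

#' Read and write plain-text spike-time files
#'
#' One event time (seconds) per line.
#'
#' @param x A [spike_train()].
#' @param path File path.
#' @param duration_s Recording span to attach on read; defaults to the last
#'   spike time when not given.
#' @return `write_spike_times()` returns `path` invisibly;
#'   `read_spike_times()` a [spike_train()].
#' @export
write_spike_times <- function(x, path) {
  stopifnot(inherits(x, "spike_train"))
  writeLines(sprintf("%.9f", x$times_s), path)
  invisible(path)
}

#' @rdname write_spike_times
#' @export
read_spike_times <- function(path, duration_s = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  times <- suppressWarnings(as.numeric(lines))
  if (anyNA(times)) {
    stop("non-numeric spike time at line ", which(is.na(times))[1], call. = FALSE)
  }
  if (is.null(duration_s)) {
    duration_s <- if (length(times)) max(times) else 1
  }
  spike_train(times, duration_s)
}
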
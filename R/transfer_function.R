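#' Amplifier transfer function on a frequency grid
#'
#' Gain and phase of a linear acquisition chain, tabulated on a strictly
#' increasing grid of positive frequencies. The phase convention is that a
#' positive phase means the output *leads* the input, which is what an
#' analog high-pass stage does below and around its cutoff. Phase must be
#' stored unwrapped: adjacent grid points may not jump by more than pi.
#'
#' @param freqs_hz Strictly increasing positive frequencies (Hz).
#' @param gain Linear amplitude ratio at each frequency (dimensionless, >= 0).
#' @param phase_rad Unwrapped phase shift at each frequency (radians).
#' @param meta Free-form provenance list (model description, calibration
#'   source, ...).
#' @return An object of class `transfer_function`.
#' @seealso [evaluate_model()], [interpolate_tf()], [read_tf_csv()]
#' @export
transfer_function <- function(freqs_hz, gain, phase_rad, meta = list()) {
  freqs_hz <- as.numeric(freqs_hz)
  gain <- as.numeric(gain)
  phase_rad <- as.numeric(phase_rad)
  n <- length(freqs_hz)
  if (n < 1L) stop("transfer function table must not be empty", call. = FALSE)
  if (length(gain) != n || length(phase_rad) != n) {
    stop("`freqs_hz`, `gain` and `phase_rad` must have equal length", call. = FALSE)
  }
  if (!all(is.finite(freqs_hz)) || any(freqs_hz <= 0)) {
    stop("frequencies must be finite and > 0", call. = FALSE)
  }
  if (n > 1L && any(diff(freqs_hz) <= 0)) {
    stop("frequencies must be strictly increasing", call. = FALSE)
  }
  if (!all(is.finite(gain)) || any(gain < 0)) {
    stop("gain must be finite and >= 0 everywhere", call. = FALSE)
  }
  if (!all(is.finite(phase_rad))) {
    stop("phase must be finite everywhere", call. = FALSE)
  }
  if (n > 1L && any(abs(diff(phase_rad)) > pi + 1e-9)) {
    stop("phase must be unwrapped: adjacent grid points jump by more than pi",
         call. = FALSE)
  }
  structure(list(freqs_hz = freqs_hz, gain = gain, phase_rad = phase_rad,
                 meta = meta),
            class = "transfer_function")
}

#' @export
print.transfer_function <- function(x, ...) {
  cat(sprintf("<transfer_function> %d points, %.4g-%.4g Hz\n",
              length(x$freqs_hz), min(x$freqs_hz), max(x$freqs_hz)))
  if (!is.null(x$meta$label)) cat("  source:", x$meta$label, "\n")
  invisible(x)
}

#' @export
plot.transfer_function <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$freqs_hz, x$gain, log = "x", type = "l",
                 xlab = "frequency (Hz)", ylab = "gain", ...)
  graphics::plot(x$freqs_hz, x$phase_rad, log = "x", type = "l",
                 xlab = "frequency (Hz)", ylab = "phase (rad)", ...)
  invisible(x)
}

#' Parametric analog filter models
#'
#' A parametric description of the analog filtering in an acquisition
#' front-end: a single Butterworth high- or low-pass stage, or a cascade of
#' stages whose total response is the product of the stage responses.
#' Filters are represented by their frequency response only (the analog
#' prototype evaluated at real frequencies); no time-domain recursion or
#' digital design is involved.
#'
#' @param kind One of `"first_order_highpass"`, `"butterworth_highpass"`,
#'   `"butterworth_lowpass"`, `"cascade"`.
#' @param cutoff_hz Positive cutoff frequency (-3 dB point) of the stage.
#' @param order Positive integer filter order (`first_order_highpass`
#'   requires 1).
#' @param stages For `kind = "cascade"`, a non-empty list of `filter_model`
#'   objects.
#' @return An object of class `filter_model`.
#' @export
#' @examples
#' m <- filter_model("first_order_highpass", cutoff_hz = 1)
#' evaluate_model(m, c(0.1, 1, 10))
filter_model <- function(kind = c("first_order_highpass", "butterworth_highpass",
                                  "butterworth_lowpass", "cascade"),
                         cutoff_hz = NULL, order = 1L, stages = NULL) {
  kind <- match.arg(kind)
  if (kind == "cascade") {
    if (!is.list(stages) || length(stages) < 1L ||
        !all(vapply(stages, inherits, logical(1), "filter_model"))) {
      stop("a cascade needs a non-empty list of filter_model stages", call. = FALSE)
    }
    return(structure(list(kind = kind, stages = stages), class = "filter_model"))
  }
  if (!is.numeric(cutoff_hz) || length(cutoff_hz) != 1L || !is.finite(cutoff_hz) ||
      cutoff_hz <= 0) {
    stop("`cutoff_hz` must be a single positive number", call. = FALSE)
  }
  order <- as.integer(order)
  if (is.na(order) || order < 1L) stop("`order` must be >= 1", call. = FALSE)
  if (kind == "first_order_highpass" && order != 1L) {
    stop("first_order_highpass has order 1 by definition", call. = FALSE)
  }
  structure(list(kind = kind, cutoff_hz = cutoff_hz, order = order),
            class = "filter_model")
}

#' @export
print.filter_model <- function(x, ...) {
  if (x$kind == "cascade") {
    cat("<filter_model> cascade of", length(x$stages), "stages\n")
    for (s in x$stages) {
      cat(sprintf("  %s @ %g Hz (order %d)\n", s$kind, s$cutoff_hz, s$order))
    }
  } else {
    cat(sprintf("<filter_model> %s @ %g Hz (order %d)\n",
                x$kind, x$cutoff_hz, x$order))
  }
  invisible(x)
}

#' Named acquisition-system presets
#'
#' Stand-ins for the analog front-ends of common acquisition systems: a
#' first-order high-pass at the system's nominal cutoff cascaded with a
#' first-order low-pass at 7.5 kHz. The true filter topology and order of
#' commercial systems are not published, and nominally equal cutoffs can
#' hide very different phase behaviour, so these presets are a modelling
#' assumption: any real system should be calibrated with
#' [synthesize_calibration()]-style sine measurements before its recordings
#' are corrected.
#'
#' @param name `"cerebus-like"` (0.3 Hz HP), `"openephys-1hz"` (1 Hz HP) or
#'   `"openephys-0.1hz"` (0.1 Hz HP); each cascaded with a 7.5 kHz LP.
#' @return A [filter_model()] cascade.
#' @export
filter_preset <- function(name = c("cerebus-like", "openephys-1hz",
                                   "openephys-0.1hz")) {
  name <- match.arg(name)
  hp_cut <- switch(name,
    "cerebus-like" = 0.3,
    "openephys-1hz" = 1,
    "openephys-0.1hz" = 0.1
  )
  filter_model("cascade", stages = list(
    filter_model("first_order_highpass", cutoff_hz = hp_cut),
    filter_model("butterworth_lowpass", cutoff_hz = 7500, order = 1L)
  ))
}

# Normalized Butterworth poles (left half plane, |s_k| = 1).
.butter_poles <- function(order) {
  k <- seq_len(order)
  exp(1i * pi * (2 * k + order - 1) / (2 * order))
}

# Gain and naturally-unwrapped phase of one stage at positive frequencies f.
# The low-pass prototype H(S) = 1/prod(S - s_k) is evaluated at S = i f/fc;
# the high-pass variant substitutes S -> fc/s, i.e. S = -i fc/f. Each pole
# factor has positive real part, so its argument stays in (-pi/2, pi/2) and
# the summed phase is continuous in f without explicit unwrapping.
.stage_response <- function(model, f) {
  S <- switch(model$kind,
    butterworth_lowpass = 1i * f / model$cutoff_hz,
    first_order_highpass = ,
    butterworth_highpass = -1i * model$cutoff_hz / f,
    stop("unknown filter kind: ", model$kind, call. = FALSE)
  )
  gain <- rep(1, length(f))
  phase <- rep(0, length(f))
  for (p in .butter_poles(model$order)) {
    d <- S - p
    gain <- gain / Mod(d)
    phase <- phase - Arg(d)
  }
  list(gain = gain, phase = phase)
}

.model_response <- function(model, f) {
  if (model$kind == "cascade") {
    gain <- rep(1, length(f))
    phase <- rep(0, length(f))
    for (s in model$stages) {
      r <- .model_response(s, f)
      gain <- gain * r$gain
      phase <- phase + r$phase
    }
    list(gain = gain, phase = phase)
  } else {
    .stage_response(model, f)
  }
}

.model_label <- function(model) {
  if (model$kind == "cascade") {
    paste0("cascade(", paste(vapply(model$stages, .model_label, character(1)),
                             collapse = " * "), ")")
  } else {
    sprintf("%s@%gHz^%d", model$kind, model$cutoff_hz, model$order)
  }
}

#' Evaluate a parametric filter model on a frequency grid
#'
#' Computes the analog prototype's gain and phase at each requested
#' frequency. Cascades multiply gains and add phases. The returned phase is
#' continuous (unwrapped) by construction.
#'
#' @param model A [filter_model()].
#' @param freqs_hz Positive frequencies (Hz) to evaluate at.
#' @return A [transfer_function()].
#' @export
evaluate_model <- function(model, freqs_hz) {
  if (!inherits(model, "filter_model")) {
    stop("`model` must be a filter_model", call. = FALSE)
  }
  freqs_hz <- as.numeric(freqs_hz)
  if (length(freqs_hz) < 1L || !all(is.finite(freqs_hz)) || any(freqs_hz <= 0)) {
    stop("all frequencies must be positive and finite", call. = FALSE)
  }
  if (is.unsorted(freqs_hz, strictly = TRUE)) {
    stop("frequencies must be strictly increasing", call. = FALSE)
  }
  r <- .model_response(model, freqs_hz)
  transfer_function(freqs_hz, r$gain, r$phase,
                    meta = list(label = .model_label(model), model = model))
}

#' Interpolate a transfer function onto a new frequency grid
#'
#' Gain is interpolated linearly in (log-frequency, dB-gain) coordinates and
#' phase linearly in (log-frequency, unwrapped phase), which is the natural
#' geometry for calibration grids spanning several decades. Beyond the
#' tabulated range the endpoint values are held constant. Interpolation is
#' exact (identity) at the tabulated frequencies.
#'
#' @param tf A [transfer_function()].
#' @param target_freqs_hz Positive frequencies (Hz) to interpolate onto.
#' @return A [transfer_function()] on the target grid.
#' @export
interpolate_tf <- function(tf, target_freqs_hz) {
  if (!inherits(tf, "transfer_function")) {
    stop("`tf` must be a transfer_function", call. = FALSE)
  }
  target_freqs_hz <- as.numeric(target_freqs_hz)
  if (length(target_freqs_hz) < 1L || any(!is.finite(target_freqs_hz)) ||
      any(target_freqs_hz <= 0)) {
    stop("target frequencies must be positive and finite", call. = FALSE)
  }
  if (is.unsorted(target_freqs_hz, strictly = TRUE)) {
    stop("target frequencies must be strictly increasing", call. = FALSE)
  }
  lf <- log(tf$freqs_hz)
  lt <- log(target_freqs_hz)
  if (length(tf$freqs_hz) == 1L) {
    gain <- rep(tf$gain, length(target_freqs_hz))
    phase <- rep(tf$phase_rad, length(target_freqs_hz))
  } else {
    # dB floor keeps log interpolation defined when a tabulated gain is 0
    db <- 20 * log10(pmax(tf$gain, 1e-300))
    gain <- 10^(stats::approx(lf, db, xout = lt, rule = 2)$y / 20)
    phase <- stats::approx(lf, tf$phase_rad, xout = lt, rule = 2)$y
  }
  transfer_function(target_freqs_hz, gain, phase, meta = tf$meta)
}

#' Read and write transfer-function CSV tables
#'
#' The on-disk format is a UTF-8 CSV with header exactly
#' `freq_hz,gain,phase_rad` and `.` as decimal separator. Rows are sorted by
#' frequency on read; a write/read round trip preserves values to 12
#' significant digits.
#'
#' @param tf A [transfer_function()].
#' @param path CSV file path.
#' @return `write_tf_csv()` returns `path` invisibly; `read_tf_csv()` a
#'   [transfer_function()].
#' @export
write_tf_csv <- function(tf, path) {
  stopifnot(inherits(tf, "transfer_function"))
  lines <- c("freq_hz,gain,phase_rad",
             sprintf("%.15g,%.15g,%.15g", tf$freqs_hz, tf$gain, tf$phase_rad))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_tf_csv
#' @export
read_tf_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  required <- c("freq_hz", "gain", "phase_rad")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("transfer-function CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num <- lapply(tab[required], function(col) suppressWarnings(as.numeric(col)))
  for (col in required) {
    bad <- which(is.na(num[[col]]) & !is.na(tab[[col]]) | is.na(tab[[col]]))
    if (length(bad)) {
      stop(sprintf("non-numeric value in column `%s` at data row %d of %s",
                   col, bad[1], path), call. = FALSE)
    }
  }
  ord <- order(num$freq_hz)
  freqs <- num$freq_hz[ord]
  dup <- which(diff(freqs) == 0)
  if (length(dup)) {
    stop(sprintf("duplicate frequency %g Hz at data row %d of %s",
                 freqs[dup[1]], ord[dup[1] + 1], path), call. = FALSE)
  }
  transfer_function(freqs, num$gain[ord], num$phase_rad[ord],
                    meta = list(label = paste0("csv:", basename(path))))
}
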
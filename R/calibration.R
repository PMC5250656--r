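#' Sine-wave calibration record
#'
#' One calibration measurement: the amplifier's output while a sine of
#' known frequency and amplitude was delivered to its input, together with
#' marker events at the *extrema* of the input sine (the role played by a
#' function generator's TTL output in a bench measurement). Markers rather
#' than zero crossings define the phase reference: zero phase means an
#' unfiltered sine whose positive peaks align with alternate markers.
#'
#' @param output_signal [lfp_signal()]: the recorded amplifier output.
#' @param marker_times_s Sorted times (s) of input-sine extrema; consecutive
#'   markers must be half an input period apart (within 10%).
#' @param input_freq_hz Nominal input sine frequency (Hz).
#' @param input_amplitude Known input amplitude, in the same units as the
#'   output after gain normalization.
#' @return An object of class `calibration_record`.
#' @seealso [synthesize_calibration()], [estimate_point()], [estimate_tf()]
#' @export
calibration_record <- function(output_signal, marker_times_s, input_freq_hz,
                               input_amplitude) {
  if (!inherits(output_signal, "lfp_signal")) {
    stop("`output_signal` must be an lfp_signal", call. = FALSE)
  }
  marker_times_s <- as.numeric(marker_times_s)
  if (length(marker_times_s) < 2L || any(diff(marker_times_s) <= 0)) {
    stop("`marker_times_s` must be >= 2 strictly increasing times", call. = FALSE)
  }
  if (!is.numeric(input_freq_hz) || input_freq_hz <= 0) {
    stop("`input_freq_hz` must be positive", call. = FALSE)
  }
  if (!is.numeric(input_amplitude) || input_amplitude <= 0) {
    stop("`input_amplitude` must be positive", call. = FALSE)
  }
  half_period <- 0.5 / input_freq_hz
  spacing <- diff(marker_times_s)
  if (any(abs(spacing - half_period) > 0.1 * half_period)) {
    stop("marker spacing deviates more than 10% from half the input period",
         call. = FALSE)
  }
  if (signal_duration(output_signal) < 3 / input_freq_hz) {
    stop("output signal must cover at least 3 full input periods", call. = FALSE)
  }
  structure(list(output_signal = output_signal,
                 marker_times_s = marker_times_s,
                 input_freq_hz = as.numeric(input_freq_hz),
                 input_amplitude = as.numeric(input_amplitude)),
            class = "calibration_record")
}

#' Simulate a sine-wave calibration measurement
#'
#' Software stand-in for the bench procedure of feeding a function
#' generator into an amplifier head-stage: the output is the model-filtered
#' sine (analytic amplitude scaling and phase shift at the test frequency)
#' plus white Gaussian noise, and the markers are the exact extrema of the
#' clean input sine.
#'
#' @param model A [filter_model()] emulating the amplifier.
#' @param freq_hz Input sine frequency (Hz).
#' @param amplitude Input sine amplitude.
#' @param duration_s Record length; must cover >= 3 input periods.
#' @param fs_hz Sampling rate; must exceed `20 * freq_hz`.
#' @param noise_sd Standard deviation of additive white noise on the output.
#' @param seed Optional RNG seed; a fixed seed makes the record reproducible.
#' @return A [calibration_record()].
#' @export
#' @examples
#' rec <- synthesize_calibration(filter_model("first_order_highpass", 1),
#'                               freq_hz = 1, amplitude = 5000,
#'                               duration_s = 10, fs_hz = 1000)
#' estimate_point(rec)
synthesize_calibration <- function(model, freq_hz, amplitude, duration_s, fs_hz,
                                   noise_sd = 0, seed = NULL) {
  if (!inherits(model, "filter_model")) {
    stop("`model` must be a filter_model", call. = FALSE)
  }
  if (duration_s < 3 / freq_hz) {
    stop("`duration_s` must cover at least 3 periods of `freq_hz`", call. = FALSE)
  }
  if (fs_hz <= 20 * freq_hz) {
    stop("`fs_hz` must exceed 20 * freq_hz", call. = FALSE)
  }
  r <- .model_response(model, freq_hz)
  n <- round(duration_s * fs_hz)
  t <- (seq_len(n) - 1) / fs_hz
  clean <- amplitude * r$gain * sin(2 * pi * freq_hz * t + r$phase)
  noise <- if (noise_sd > 0) {
    .with_seed(seed, stats::rnorm(n, sd = noise_sd))
  } else {
    numeric(n)
  }
  # extrema of the clean input sine sin(2*pi*f*t): maxima at (k + 1/4)/f,
  # minima at (k + 3/4)/f
  k_max <- ceiling(duration_s * freq_hz)
  markers <- sort(c((seq_len(k_max) - 0.75) / freq_hz,
                    (seq_len(k_max) - 0.25) / freq_hz))
  markers <- markers[markers <= duration_s - 1 / fs_hz]
  calibration_record(lfp_signal(clean + noise, fs_hz), markers, freq_hz, amplitude)
}

#' Estimate gain and phase from one calibration record
#'
#' Fits `A * sin(2*pi*f*t + psi) + offset` to the output by linear least
#' squares at the known input frequency (in-phase, quadrature and offset
#' regressors), then references the fitted phase to the extrema markers.
#' Whether the first marker is a maximum or a minimum of the input is
#' decided from the sign of the fitted waveform at that marker. The fit is
#' exact on noiseless input and invariant to any DC offset of the output.
#'
#' @param record A [calibration_record()].
#' @return A list with elements `gain` (fitted amplitude over input
#'   amplitude) and `phase_rad` (output phase relative to the input,
#'   in `(-pi, pi]`; positive = output leads).
#' @export
estimate_point <- function(record) {
  if (!inherits(record, "calibration_record")) {
    stop("`record` must be a calibration_record", call. = FALSE)
  }
  sig <- record$output_signal
  y <- sig$samples
  if (stats::sd(y) == 0) {
    stop("estimation failed: output signal is flat", call. = FALSE)
  }
  w <- 2 * pi * record$input_freq_hz
  t <- signal_times(sig)
  X <- cbind(1, sin(w * t), cos(w * t))
  beta <- stats::lm.fit(X, y)$coefficients
  A <- sqrt(beta[2]^2 + beta[3]^2)
  if (!is.finite(A) || A < .Machine$double.eps * max(abs(y))) {
    stop("estimation failed: no component at the input frequency", call. = FALSE)
  }
  psi <- atan2(beta[3], beta[2])           # output = A*sin(w*t + psi) + c
  t0 <- record$marker_times_s[1]
  fitted0 <- beta[2] * sin(w * t0) + beta[3] * cos(w * t0)
  # input phase at the first marker is +pi/2 (maximum) or -pi/2 (minimum)
  input_phase0 <- if (fitted0 >= 0) pi / 2 else -pi / 2
  phase <- .wrap_pi((w * t0 + psi) - input_phase0)
  list(gain = unname(A / record$input_amplitude), phase_rad = unname(phase))
}

#' Assemble a transfer function from calibration records
#'
#' Runs [estimate_point()] on each record, sorts the resulting (gain, phase)
#' points by frequency and unwraps the phase across frequencies.
#'
#' @param records List of [calibration_record()] objects at >= 2 distinct
#'   frequencies (any order).
#' @return A [transfer_function()] tabulated at the calibration frequencies.
#' @export
estimate_tf <- function(records) {
  if (!is.list(records) || length(records) < 2L ||
      !all(vapply(records, inherits, logical(1), "calibration_record"))) {
    stop("`records` must be a list of >= 2 calibration_record objects",
         call. = FALSE)
  }
  freqs <- vapply(records, function(r) r$input_freq_hz, numeric(1))
  if (anyDuplicated(freqs)) {
    stop("calibration records must be at distinct frequencies", call. = FALSE)
  }
  pts <- lapply(records, estimate_point)
  ord <- order(freqs)
  transfer_function(
    freqs[ord],
    vapply(pts, `[[`, numeric(1), "gain")[ord],
    .unwrap(vapply(pts, `[[`, numeric(1), "phase_rad")[ord]),
    meta = list(label = sprintf("calibration (%d records)", length(records)))
  )
}

#' Default logarithmic calibration grid
#'
#' Log-spaced test frequencies spanning 0.03-30 Hz, the band where analog
#' high-pass stages of acquisition systems distort phase appreciably.
#'
#' @param n Number of frequencies.
#' @return Numeric vector of frequencies (Hz).
#' @export
calibration_grid <- function(n = 7) {
  exp(seq(log(0.03), log(30), length.out = n))
}
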
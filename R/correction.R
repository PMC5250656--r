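# Frequency-domain application and phase-only inversion of a transfer
# function. Both operations use a single whole-record FFT: the spectrum is
# multiplied bin-by-bin and inverse transformed, with conjugate-symmetric
# handling of negative frequencies so the output stays real. Tabulated
# transfer functions are moved onto the record's FFT bin grid with
# interpolate_tf(); filter_model inputs are evaluated exactly on that grid.
#
# Conventions for the two bins without a well-defined phase:
#   * DC: a high-pass filter's phase is undefined at 0 Hz; the DC bin is
#     multiplied by the gain at the lowest available frequency with phase 0
#     (phase_correct leaves it untouched).
#   * Nyquist: multiplied by its gain with phase 0, keeping the bin real.
# These conventions make phase_correct(apply_tf(v, H), H) agree exactly
# with gain-only filtering at every bin.

# Gain/phase of `tf` (transfer_function or filter_model) on the positive
# FFT bins of an n-sample record at rate fs, plus Nyquist when n is even.
.tf_on_grid <- function(tf, n, fs_hz) {
  k <- seq_len(ceiling(n / 2) - 1)
  f <- k * fs_hz / n
  even <- n %% 2 == 0
  f_all <- if (even) c(f, fs_hz / 2) else f
  r <- if (inherits(tf, "filter_model")) {
    .model_response(tf, f_all)
  } else if (inherits(tf, "transfer_function")) {
    it <- interpolate_tf(tf, f_all)
    list(gain = it$gain, phase = it$phase_rad)
  } else {
    stop("`tf` must be a transfer_function or filter_model", call. = FALSE)
  }
  list(k = k,
       gain = r$gain[seq_along(k)], phase = r$phase[seq_along(k)],
       nyq_gain = if (even) r$gain[length(f_all)] else NULL)
}

# Shared worker: multiply the record's spectrum by per-bin `mult` (positive
# bins), its conjugate on negative bins, and real factors on DC / Nyquist.
.fft_apply <- function(v, mult, dc_mult, nyq_mult, pad_mirror = FALSE) {
  s <- v$samples
  n0 <- length(s)
  if (pad_mirror) s <- c(s, rev(s))
  n <- length(s)
  M <- complex(real = rep(1, n))
  k <- seq_len(ceiling(n / 2) - 1)
  M[k + 1] <- mult
  M[n + 1 - k] <- Conj(mult)
  M[1] <- dc_mult
  if (n %% 2 == 0) M[n / 2 + 1] <- nyq_mult
  out <- Re(stats::fft(stats::fft(s) * M, inverse = TRUE)) / n
  lfp_signal(out[seq_len(n0)], v$fs_hz, t0_s = v$t0_s, units = v$units)
}

#' Filter a signal with a transfer function (forward distortion)
#'
#' Multiplies each positive-frequency bin of the record's spectrum by
#' `gain(f) * exp(i * phase(f))` — the frequency-domain equivalent of
#' passing the signal through the amplifier the transfer function
#' describes. The whole record is transformed in one FFT, which treats it
#' as circular; for short records `pad_mirror = TRUE` mirror-pads before
#' transforming to soften wrap-around effects.
#'
#' @param v_in An [lfp_signal()] with at least 2 samples.
#' @param tf A [transfer_function()] (interpolated onto the FFT grid) or a
#'   [filter_model()] (evaluated exactly on it).
#' @param pad_mirror Mirror-pad the record before transforming (off by
#'   default).
#' @return The filtered [lfp_signal()], same length and rate.
#' @seealso [phase_correct()]
#' @export
apply_tf <- function(v_in, tf, pad_mirror = FALSE) {
  if (!inherits(v_in, "lfp_signal")) {
    stop("`v_in` must be an lfp_signal", call. = FALSE)
  }
  n_eff <- length(v_in$samples) * (1L + pad_mirror)
  if (length(v_in$samples) < 2L) {
    stop("signal must contain at least 2 samples", call. = FALSE)
  }
  g <- .tf_on_grid(tf, n_eff, v_in$fs_hz)
  .fft_apply(v_in, g$gain * exp(1i * g$phase),
             dc_mult = g$gain[1],
             nyq_mult = if (is.null(g$nyq_gain)) 1 else g$nyq_gain,
             pad_mirror = pad_mirror)
}

#' Undo a transfer function's phase distortion (phase-only correction)
#'
#' Multiplies each positive-frequency bin of the recorded spectrum by
#' `exp(-i * phase(f))`, cancelling the phase shift the amplifier
#' introduced while leaving every bin's power — including the low-frequency
#' attenuation — untouched. Inverting the gain as well would amplify
#' low-frequency noise, so the power loss is deliberately retained; see
#' `invert_gain` to opt in regardless.
#'
#' @inheritParams apply_tf
#' @param v_out The recorded (distorted) [lfp_signal()].
#' @param invert_gain Also divide each bin by its gain (off by default;
#'   gains are floored at 1e-6 of the maximum to avoid blow-up).
#' @return The corrected [lfp_signal()], same length and rate.
#' @export
#' @examples
#' v <- lfp_signal(rnorm(1024), fs_hz = 250)
#' h <- filter_preset("openephys-1hz")
#' v_rec <- apply_tf(v, h)
#' v_corr <- phase_correct(v_rec, h)
phase_correct <- function(v_out, tf, invert_gain = FALSE, pad_mirror = FALSE) {
  if (!inherits(v_out, "lfp_signal")) {
    stop("`v_out` must be an lfp_signal", call. = FALSE)
  }
  if (length(v_out$samples) < 2L) {
    stop("signal must contain at least 2 samples", call. = FALSE)
  }
  n_eff <- length(v_out$samples) * (1L + pad_mirror)
  g <- .tf_on_grid(tf, n_eff, v_out$fs_hz)
  mult <- exp(-1i * g$phase)
  dc <- 1
  nyq <- 1
  if (invert_gain) {
    floor_g <- 1e-6 * max(g$gain, g$nyq_gain)
    mult <- mult / pmax(g$gain, floor_g)
    dc <- 1 / max(g$gain[1], floor_g)
    if (!is.null(g$nyq_gain)) nyq <- 1 / max(g$nyq_gain, floor_g)
  }
  .fft_apply(v_out, mult, dc_mult = dc, nyq_mult = nyq, pad_mirror = pad_mirror)
}
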
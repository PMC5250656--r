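#' Target spectrum and coherence for the signal-pair generator
#'
#' A one-sided power spectral density `P(f)` (units^2/Hz, normalized so
#' that its integral over frequency equals the signal variance) and a
#' magnitude coherence `C(f)` in `[0, 1]`, tabulated on a shared frequency
#' grid. [generate_pair()] interpolates both onto the FFT bin grid implied
#' by the requested duration and sampling rate.
#'
#' @param freqs_hz Strictly increasing positive frequencies (Hz).
#' @param power Target one-sided PSD per frequency (>= 0).
#' @param coherence Target magnitude coherence per frequency (in `[0, 1]`).
#' @param meta Free-form provenance list.
#' @return An object of class `spectral_spec`.
#' @seealso [make_spectral_spec()], [generate_pair()]
#' @export
spectral_spec <- function(freqs_hz, power, coherence, meta = list()) {
  freqs_hz <- as.numeric(freqs_hz)
  power <- as.numeric(power)
  coherence <- as.numeric(coherence)
  n <- length(freqs_hz)
  if (n < 2L) stop("a spectral spec needs at least 2 grid points", call. = FALSE)
  if (length(power) != n || length(coherence) != n) {
    stop("`power` and `coherence` must share the frequency grid", call. = FALSE)
  }
  if (!all(is.finite(freqs_hz)) || any(freqs_hz <= 0) || any(diff(freqs_hz) <= 0)) {
    stop("frequencies must be positive and strictly increasing", call. = FALSE)
  }
  if (!all(is.finite(power)) || any(power < 0)) {
    stop("power must be finite and >= 0 everywhere", call. = FALSE)
  }
  if (!all(is.finite(coherence)) || any(coherence < 0) || any(coherence > 1)) {
    stop("coherence must lie in [0, 1] everywhere", call. = FALSE)
  }
  structure(list(freqs_hz = freqs_hz, power = power, coherence = coherence,
                 meta = meta),
            class = "spectral_spec")
}

#' @export
print.spectral_spec <- function(x, ...) {
  cat(sprintf(
    "<spectral_spec> %d points, %.4g-%.4g Hz; total power %.4g, max coherence %.3f\n",
    length(x$freqs_hz), min(x$freqs_hz), max(x$freqs_hz),
    sum((x$power[-1] + x$power[-length(x$power)]) / 2 * diff(x$freqs_hz)),
    max(x$coherence)
  ))
  invisible(x)
}

# Raised-cosine transition: 1 below `lo`, 0 above `hi`, half-cosine between.
.rc_taper <- function(f, lo, hi) {
  ifelse(f <= lo, 1,
         ifelse(f >= hi, 0, 0.5 * (1 + cos(pi * (f - lo) / (hi - lo)))))
}

#' Build a spectral spec from a named family
#'
#' The `powerlaw_knee` family emulates an LFP-like spectrum:
#' `P(f) = A / (1 + (f / knee_hz)^exponent) + hf_floor`, flat below the
#' knee, falling as a power law above it and bottoming out on a broadband
#' floor (the wideband background any real recording carries — at the
#' default 1 unit^2/Hz it contributes about 2% of the variance but most of
#' the fast fluctuations, so that threshold crossings of a generated signal
#' occur at multi-unit-like rates of a few Hz). The whole spectrum is
#' optionally rescaled at low frequencies by `lf_mult` (fully below
#' `mult_lo_hz`, tapering to no effect at `mult_hi_hz`). A broad Gaussian
#' bump (`osc_amp` at `osc_freq_hz`, width `osc_bw_hz`) adds the kind of
#' slow rhythmic component (3-8 Hz) that is prominent in rodent cortical
#' LFP. Scaling `lf_mult` therefore changes band power below
#' `mult_lo_hz` by exactly that factor while leaving power above
#' `mult_hi_hz` untouched — the knob used to sweep how strongly
#' low-frequency-weighted the pair is. Coherence is a raised-cosine band:
#' `c_max` below `band_lo_hz`, tapering to zero at `band_hi_hz`.
#'
#' Defaults describe a cortical-LFP-like pair: a 0.7 Hz knee with an
#' `f^-3` tail, a broad low-amplitude 5 Hz rhythm and a small wideband
#' floor (about 70 units RMS in total), plus strong low-frequency
#' coherence (0.9 below 2 Hz, gone by 20 Hz) — which yields a symmetric
#' central-trough cross-correlation a few hundred milliseconds wide.
#'
#' @param family `"powerlaw_knee"`, `"flat"`, or `"tabulated"`.
#' @param amplitude PSD amplitude `A` (units^2/Hz): plateau value for
#'   `powerlaw_knee`, constant level for `flat`.
#' @param knee_hz,exponent Knee frequency and high-frequency exponent of
#'   `powerlaw_knee`.
#' @param hf_floor Broadband floor of `powerlaw_knee` (units^2/Hz).
#' @param osc_amp,osc_freq_hz,osc_bw_hz Amplitude (units^2/Hz), center and
#'   Gaussian width of the slow rhythmic bump (set `osc_amp = 0` to drop it).
#' @param lf_mult,mult_lo_hz,mult_hi_hz Low-frequency power multiplier and
#'   its raised-cosine transition band.
#' @param c_max,band_lo_hz,band_hi_hz Coherence plateau and its
#'   raised-cosine rolloff band.
#' @param freqs_hz Frequency grid; defaults to 1200 log-spaced points
#'   covering 1e-4 to 1e4 Hz. For `family = "tabulated"` this grid, `power`
#'   and `coherence` are taken verbatim.
#' @param power,coherence Tables for `family = "tabulated"`.
#' @return A [spectral_spec()].
#' @export
#' @examples
#' sp <- make_spectral_spec()
#' sp3 <- make_spectral_spec(lf_mult = 3) # triple power below 0.5 Hz
make_spectral_spec <- function(family = c("powerlaw_knee", "flat", "tabulated"),
                               amplitude = 5000, knee_hz = 0.7, exponent = 3,
                               hf_floor = 1,
                               osc_amp = 50, osc_freq_hz = 5, osc_bw_hz = 3,
                               lf_mult = 1, mult_lo_hz = 0.5, mult_hi_hz = 2,
                               c_max = 0.9, band_lo_hz = 2, band_hi_hz = 20,
                               freqs_hz = NULL, power = NULL, coherence = NULL) {
  family <- match.arg(family)
  if (family == "tabulated") {
    if (is.null(freqs_hz) || is.null(power) || is.null(coherence)) {
      stop("tabulated family needs `freqs_hz`, `power` and `coherence`",
           call. = FALSE)
    }
    return(spectral_spec(freqs_hz, power, coherence,
                         meta = list(family = "tabulated")))
  }
  for (p in c(amplitude, knee_hz, exponent, hf_floor, osc_amp, osc_freq_hz,
              osc_bw_hz, lf_mult, mult_lo_hz, mult_hi_hz, c_max, band_lo_hz,
              band_hi_hz)) {
    if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 0) {
      stop("family parameters must be single non-negative numbers", call. = FALSE)
    }
  }
  if (mult_hi_hz <= mult_lo_hz || band_hi_hz <= band_lo_hz) {
    stop("transition bands need hi > lo", call. = FALSE)
  }
  if (c_max > 1) stop("`c_max` must be <= 1", call. = FALSE)
  if (is.null(freqs_hz)) {
    freqs_hz <- exp(seq(log(1e-4), log(1e4), length.out = 1200))
  }
  pw <- switch(family,
    flat = rep(amplitude, length(freqs_hz)),
    powerlaw_knee = {
      base <- amplitude / (1 + (freqs_hz / knee_hz)^exponent) + hf_floor +
        osc_amp * exp(-(freqs_hz - osc_freq_hz)^2 / (2 * osc_bw_hz^2))
      taper <- .rc_taper(freqs_hz, mult_lo_hz, mult_hi_hz)
      base * (lf_mult * taper + (1 - taper))
    }
  )
  coh <- c_max * .rc_taper(freqs_hz, band_lo_hz, band_hi_hz)
  spectral_spec(freqs_hz, pw, coh,
                meta = list(family = family, amplitude = amplitude,
                            knee_hz = knee_hz, exponent = exponent,
                            lf_mult = lf_mult))
}

# Interpolate spec power/coherence onto FFT bin frequencies (linear with
# endpoint hold).
.spec_on_bins <- function(spec, f) {
  P <- .interp_hold(spec$freqs_hz, spec$power, f)
  C <- .interp_hold(spec$freqs_hz, spec$coherence, f)
  if (any(C < 0 | C > 1)) {
    stop("coherence outside [0, 1] after interpolation", call. = FALSE)
  }
  list(P = pmax(P, 0), C = C)
}

#' Generate a signal pair with prescribed spectrum and coherence
#'
#' Constructs both signals in the frequency domain. The first signal's
#' spectrum is `X(f) = sqrt(P(f)) * exp(i*phi(f))` with phases drawn
#' independently and uniformly on `[0, 2*pi)` per positive-frequency bin;
#' the second is `Y(f) = -C(f) * X(f) + Y2(f)` where `Y2` carries power
#' `(1 - C(f)^2) * P(f)` with its own independent phases. Negative-frequency
#' bins are conjugate-symmetric, the DC bin is zero (both signals are
#' zero-mean by construction) and the Nyquist bin is real with random sign.
#' The realized magnitude coherence between the outputs equals `C(f)` and
#' their cross-spectrum `-C(f) * P(f)` is real and non-positive, so the
#' pair's cross-correlation is symmetric with a central trough.
#'
#' With `spec_y` given, `y` instead receives power from `spec_y` while the
#' coherence is taken from `spec`; this varies one signal's spectrum at
#' fixed coherence.
#'
#' @param spec A [spectral_spec()] (power of `x`, and of `y` unless
#'   `spec_y` is given; coherence of the pair).
#' @param duration_s,fs_hz Record length (s) and sampling rate (Hz).
#' @param seed RNG seed; fixing it makes the pair fully reproducible.
#' @param spec_y Optional [spectral_spec()] supplying `y`'s power.
#' @return A list with elements `x` and `y`, both [lfp_signal()] objects.
#' @export
#' @examples
#' pair <- generate_pair(make_spectral_spec(), duration_s = 60,
#'                       fs_hz = 250, seed = 1)
#' cc <- cross_correlate(pair$x, pair$y, max_lag_s = 1)
generate_pair <- function(spec, duration_s, fs_hz, seed, spec_y = NULL) {
  if (!inherits(spec, "spectral_spec")) {
    stop("`spec` must be a spectral_spec", call. = FALSE)
  }
  if (!is.null(spec_y) && !inherits(spec_y, "spectral_spec")) {
    stop("`spec_y` must be a spectral_spec", call. = FALSE)
  }
  n <- round(duration_s * fs_hz)
  if (n < 8) stop("record too short: need at least 8 samples", call. = FALSE)
  k <- seq_len(ceiling(n / 2) - 1)
  f <- k * fs_hz / n
  sx <- .spec_on_bins(spec, f)
  Py <- if (is.null(spec_y)) sx$P else .spec_on_bins(spec_y, f)$P
  # |X_k| = sqrt(P * fs * n / 2) makes the one-sided periodogram equal P
  amp_x <- sqrt(sx$P * fs_hz * n / 2)
  amp_2 <- sqrt(pmax(1 - sx$C^2, 0) * Py * fs_hz * n / 2)
  ratio <- ifelse(sx$P > 0, sqrt(Py / pmax(sx$P, .Machine$double.xmin)), 0)
  even <- n %% 2 == 0
  draws <- .with_seed(seed, list(
    phi_x = stats::runif(length(k), 0, 2 * pi),
    phi_2 = stats::runif(length(k), 0, 2 * pi),
    nyq_sign = if (even) sample(c(-1, 1), 2, replace = TRUE) else c(1, 1)
  ))
  X <- amp_x * exp(1i * draws$phi_x)
  Y <- -sx$C * ratio * X + amp_2 * exp(1i * draws$phi_2)
  to_time <- function(pos, nyq) {
    full <- complex(n)
    full[k + 1] <- pos
    full[n + 1 - k] <- Conj(pos)
    if (even) full[n / 2 + 1] <- nyq
    Re(stats::fft(full, inverse = TRUE)) / n
  }
  nyq_x <- nyq_y <- 0
  if (even) {
    f_nyq <- fs_hz / 2
    sn <- .spec_on_bins(spec, f_nyq)
    Pyn <- if (is.null(spec_y)) sn$P else .spec_on_bins(spec_y, f_nyq)$P
    # Nyquist is its own conjugate: real amplitude, random sign
    nyq_x <- draws$nyq_sign[1] * sqrt(sn$P * fs_hz * n)
    nyq_y <- -sn$C * ifelse(sn$P > 0, sqrt(Pyn / sn$P), 0) * nyq_x +
      draws$nyq_sign[2] * sqrt(pmax(1 - sn$C^2, 0) * Pyn * fs_hz * n)
  }
  list(x = lfp_signal(to_time(X, nyq_x), fs_hz),
       y = lfp_signal(to_time(Y, nyq_y), fs_hz))
}

#' Derive a spike train by threshold crossing
#'
#' Computes the given percentile of the signal's samples and emits one
#' spike at each upward crossing of that threshold. Using crossings rather
#' than all supra-threshold samples avoids runs of consecutive "spikes"
#' while the signal dwells above threshold.
#'
#' @param x An [lfp_signal()].
#' @param percentile Threshold percentile in `(0, 100)`; 99 by default, so
#'   spikes mark excursions above the 99th percentile value.
#' @return A [spike_train()]. A constant signal yields an empty train with
#'   a warning.
#' @export
derive_spikes <- function(x, percentile = 99) {
  stopifnot(inherits(x, "lfp_signal"))
  if (!is.numeric(percentile) || percentile <= 0 || percentile >= 100) {
    stop("`percentile` must lie strictly between 0 and 100", call. = FALSE)
  }
  s <- x$samples
  dur <- signal_duration(x)
  if (max(s) == min(s)) {
    warning("signal is constant; returning an empty spike train")
    return(spike_train(numeric(0), dur))
  }
  thr <- as.numeric(stats::quantile(s, percentile / 100))
  idx <- which(s[-1] > thr & s[-length(s)] <= thr) + 1L
  spike_train((idx - 1) / x$fs_hz, dur)
}
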
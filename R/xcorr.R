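#' Cross-correlation / triggered-average container
#'
#' A symmetric lag axis with one value per lag: either the average product
#' of two continuous signals, or the average voltage around event times
#' (spike-triggered LFP average), in which case `n_events` counts the
#' triggers that contributed.
#'
#' @param lags_s Lag axis in seconds, symmetric about 0, strictly increasing.
#' @param values One value per lag (finite).
#' @param n_events Trigger count for spike-triggered results (`NA` for
#'   continuous cross-correlations).
#' @param meta Free-form provenance list.
#' @return An object of class `cross_correlation`.
#' @export
cross_correlation <- function(lags_s, values, n_events = NA_integer_,
                              meta = list()) {
  lags_s <- as.numeric(lags_s)
  values <- as.numeric(values)
  if (length(lags_s) != length(values) || length(lags_s) < 3L) {
    stop("`lags_s` and `values` must be equal-length vectors (>= 3)", call. = FALSE)
  }
  if (any(diff(lags_s) <= 0)) stop("lags must be strictly increasing", call. = FALSE)
  if (max(abs(lags_s + rev(lags_s))) > 1e-9 * max(abs(lags_s))) {
    stop("lag axis must be symmetric about 0", call. = FALSE)
  }
  if (!all(is.finite(values))) stop("values must be finite", call. = FALSE)
  if (!is.na(n_events) && n_events < 1) {
    stop("`n_events` must be >= 1 for spike-triggered results", call. = FALSE)
  }
  structure(list(lags_s = lags_s, values = values,
                 n_events = n_events, meta = meta),
            class = "cross_correlation")
}

#' @export
print.cross_correlation <- function(x, ...) {
  cat(sprintf("<cross_correlation> lags %.3g..%.3g s (%d points)%s\n",
              min(x$lags_s), max(x$lags_s), length(x$lags_s),
              if (!is.na(x$n_events)) sprintf(", %d events", x$n_events) else ""))
  invisible(x)
}

#' @export
plot.cross_correlation <- function(x, ...) {
  graphics::plot(x$lags_s, x$values, type = "l",
                 xlab = "lag (s)", ylab = "value", ...)
  graphics::abline(h = 0, v = 0, col = "grey70", lty = 3)
  invisible(x)
}

#' Cross-correlate two continuous signals
#'
#' Computes the unbiased, edge-truncated estimate
#' `c(tau) = mean over t of x(t) * y(t + tau)` after subtracting each
#' signal's mean, for lags up to `max_lag_s`. A positive lag means `y`
#' follows `x`. The sums are evaluated with zero-padded FFTs, so long
#' records stay fast; each lag's sum is divided by the number of
#' overlapping samples at that lag.
#'
#' @param x,y [lfp_signal()] objects with equal rates and lengths.
#' @param max_lag_s Maximum lag (s); must be below half the record length.
#' @return A [cross_correlation()].
#' @export
cross_correlate <- function(x, y, max_lag_s = 1) {
  stopifnot(inherits(x, "lfp_signal"), inherits(y, "lfp_signal"))
  if (abs(x$fs_hz - y$fs_hz) > 1e-9 * x$fs_hz) {
    stop("sampling rates differ", call. = FALSE)
  }
  n <- length(x$samples)
  if (length(y$samples) != n) stop("signal lengths differ", call. = FALSE)
  if (max_lag_s >= signal_duration(x) / 2) {
    stop("`max_lag_s` must be below half the record duration", call. = FALSE)
  }
  L <- round(max_lag_s * x$fs_hz)
  if (L < 1) stop("`max_lag_s` is below one sample interval", call. = FALSE)
  xs <- x$samples - mean(x$samples)
  ys <- y$samples - mean(y$samples)
  nfft <- stats::nextn(n + L, 2)
  X <- stats::fft(c(xs, numeric(nfft - n)))
  Y <- stats::fft(c(ys, numeric(nfft - n)))
  cc <- Re(stats::fft(Conj(X) * Y, inverse = TRUE)) / nfft
  lags <- -L:L
  sums <- c(cc[(nfft - L + 1):nfft], cc[seq_len(L + 1)])
  cross_correlation(lags / x$fs_hz, sums / (n - abs(lags)),
                    meta = list(kind = "continuous"))
}

#' Spike-triggered LFP average
#'
#' Averages mean-subtracted LFP segments centered on spike times, on a lag
#' axis spanning `+-window_s`. The result is in the LFP's own units (a
#' per-spike average voltage, not a correlation coefficient). Spikes whose
#' window would extend beyond the recording are skipped and counted in the
#' result's metadata. When the triggering events are upward threshold
#' crossings of a companion signal, the stLFP is proportional to the
#' continuous cross-correlation of the two signals.
#'
#' @param spikes A [spike_train()].
#' @param lfp An [lfp_signal()].
#' @param window_s Half-width of the averaging window (s).
#' @return A [cross_correlation()] with `n_events` set.
#' @export
st_average <- function(spikes, lfp, window_s = 1) {
  stopifnot(inherits(spikes, "spike_train"), inherits(lfp, "lfp_signal"))
  n <- length(lfp$samples)
  W <- round(window_s * lfp$fs_hz)
  if (W < 1) stop("`window_s` is below one sample interval", call. = FALSE)
  centers <- round((spikes$times_s - lfp$t0_s) * lfp$fs_hz) + 1L
  usable <- centers - W >= 1L & centers + W <= n
  if (!any(usable)) {
    stop("no spike has a full +-window inside the recording", call. = FALSE)
  }
  centers <- centers[usable]
  s <- lfp$samples - mean(lfp$samples)
  idx <- outer(-W:W, centers, `+`)
  values <- rowMeans(matrix(s[idx], nrow = 2L * W + 1L))
  cross_correlation((-W:W) / lfp$fs_hz, values, n_events = length(centers),
                    meta = list(kind = "spike_triggered",
                                n_skipped = sum(!usable)))
}

#' Symmetry diagnostic for a cross-correlation
#'
#' Sum of squared differences between the curve at `+tau` and `-tau`,
#' normalized by the curve's total sum of squares. Zero for a perfectly
#' symmetric curve.
#'
#' @param cc A [cross_correlation()].
#' @return A single non-negative number.
#' @export
asymmetry_index <- function(cc) {
  stopifnot(inherits(cc, "cross_correlation"))
  pos <- cc$values[cc$lags_s > 0]
  neg <- rev(cc$values[cc$lags_s < 0])
  m <- min(length(pos), length(neg))
  sum((pos[seq_len(m)] - neg[seq_len(m)])^2) / sum(cc$values^2)
}

#' Locate and classify the biphasic correlation shape
#'
#' Finds the central trough (minimum within `+-trough_win_s` of zero lag)
#' and the largest positive rebound at lags after it, and classifies the
#' curve as biphasic when the rebound is substantial (`ratio >
#' ratio_threshold`) and its delay after the trough falls in
#' `(peak_lo_s, peak_hi_s)` — the operational definition of the
#' trough-then-delayed-positivity shape seen in distorted spike-triggered
#' LFP averages.
#'
#' @param cc A [cross_correlation()] covering at least `+-peak_hi_s`.
#' @param trough_win_s Half-width of the search window for the trough.
#' @param ratio_threshold Minimum peak/|trough| ratio for the biphasic call.
#' @param peak_lo_s,peak_hi_s Admissible range of the peak's delay after
#'   the trough (s).
#' @return A list of class `biphasic_index` with fields `trough_lag_s`,
#'   `trough_amp`, `peak_lag_s`, `peak_amp`, `ratio` and logical `biphasic`.
#' @export
biphasic_index <- function(cc, trough_win_s = 0.1, ratio_threshold = 0.2,
                           peak_lo_s = 0.05, peak_hi_s = 1) {
  stopifnot(inherits(cc, "cross_correlation"))
  if (max(cc$lags_s) < peak_hi_s - 1e-9) {
    stop(sprintf("correlation window too short: need lags out to %g s", peak_hi_s),
         call. = FALSE)
  }
  central <- abs(cc$lags_s) <= trough_win_s
  i_tr <- which(central)[which.min(cc$values[central])]
  after <- which(cc$lags_s > cc$lags_s[i_tr])
  i_pk <- after[which.max(cc$values[after])]
  ratio <- cc$values[i_pk] / abs(cc$values[i_tr])
  offset <- cc$lags_s[i_pk] - cc$lags_s[i_tr]
  structure(list(trough_lag_s = cc$lags_s[i_tr], trough_amp = cc$values[i_tr],
                 peak_lag_s = cc$lags_s[i_pk], peak_amp = cc$values[i_pk],
                 ratio = ratio,
                 biphasic = ratio > ratio_threshold &&
                   offset > peak_lo_s && offset < peak_hi_s),
            class = "biphasic_index")
}

#' @export
print.biphasic_index <- function(x, ...) {
  cat(sprintf(
    "<biphasic_index> trough %.4g @ %+.3f s; peak %.4g @ %+.3f s; ratio %.3f -> %s\n",
    x$trough_amp, x$trough_lag_s, x$peak_amp, x$peak_lag_s, x$ratio,
    if (x$biphasic) "biphasic" else "not biphasic"))
  invisible(x)
}

# Segment starts for Welch averaging with 50% overlap.
.welch_segments <- function(n, nseg) {
  hop <- nseg %/% 2L
  if (nseg < 8L || n < nseg) {
    stop("record too short for Welch averaging: need >= 5 segments", call. = FALSE)
  }
  starts <- seq(1L, n - nseg + 1L, by = hop)
  if (length(starts) < 5L) {
    stop("record too short for Welch averaging: need >= 5 segments", call. = FALSE)
  }
  starts
}

# Averaged one-sided auto/cross spectra of one or two sample vectors.
.welch_raw <- function(xs, ys, fs, nseg) {
  starts <- .welch_segments(length(xs), nseg)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))  # Hann taper
  scale <- fs * sum(w^2)
  nb <- nseg %/% 2L + 1L
  Sxx <- Syy <- numeric(nb)
  Sxy <- complex(nb)
  for (s0 in starts) {
    seg_x <- xs[s0:(s0 + nseg - 1L)]
    Fx <- stats::fft((seg_x - mean(seg_x)) * w)[seq_len(nb)]
    Sxx <- Sxx + Mod(Fx)^2
    if (!is.null(ys)) {
      seg_y <- ys[s0:(s0 + nseg - 1L)]
      Fy <- stats::fft((seg_y - mean(seg_y)) * w)[seq_len(nb)]
      Syy <- Syy + Mod(Fy)^2
      Sxy <- Sxy + Conj(Fx) * Fy
    }
  }
  k <- length(starts)
  one_sided <- c(1, rep(2, nb - 2L), if (nseg %% 2L == 0L) 1 else 2)
  list(freq = (seq_len(nb) - 1L) * fs / nseg,
       Sxx = one_sided * Sxx / (k * scale),
       Syy = one_sided * Syy / (k * scale),
       Sxy = one_sided * Sxy / (k * scale),
       n_segments = k)
}

#' Welch spectral estimates
#'
#' Averaged-periodogram estimates over Hann-tapered, mean-removed segments
#' with 50% overlap: `welch_psd()` returns the one-sided power spectral
#' density (so the PSD integrates to the signal variance) and
#' `welch_coherence()` the magnitude coherence
#' `|S_xy| / sqrt(S_xx * S_yy)` in `[0, 1]`. These are the package's
#' empirical checks on the generator: the estimated PSD and coherence of a
#' generated pair should reproduce the spectral spec they were built from.
#'
#' @param x,y [lfp_signal()] objects (equal rate and length for coherence).
#' @param segment_s Segment length in seconds (default 10 s, i.e. 0.1 Hz
#'   resolution); the record must cover at least 5 segments.
#' @return A data.frame with column `freq_hz` and `psd` (units^2/Hz) or
#'   `coherence`; the number of averaged segments is in attribute
#'   `n_segments`.
#' @export
welch_psd <- function(x, segment_s = 10) {
  stopifnot(inherits(x, "lfp_signal"))
  nseg <- round(segment_s * x$fs_hz)
  est <- .welch_raw(x$samples, NULL, x$fs_hz, nseg)
  out <- data.frame(freq_hz = est$freq, psd = est$Sxx)
  attr(out, "n_segments") <- est$n_segments
  out
}

#' @rdname welch_psd
#' @export
welch_coherence <- function(x, y, segment_s = 10) {
  stopifnot(inherits(x, "lfp_signal"), inherits(y, "lfp_signal"))
  if (abs(x$fs_hz - y$fs_hz) > 1e-9 * x$fs_hz) {
    stop("sampling rates differ", call. = FALSE)
  }
  if (length(x$samples) != length(y$samples)) {
    stop("signal lengths differ", call. = FALSE)
  }
  nseg <- round(segment_s * x$fs_hz)
  est <- .welch_raw(x$samples, y$samples, x$fs_hz, nseg)
  coh <- Mod(est$Sxy) / sqrt(pmax(est$Sxx * est$Syy, .Machine$double.xmin))
  out <- data.frame(freq_hz = est$freq, coherence = pmin(coh, 1))
  attr(out, "n_segments") <- est$n_segments
  out
}
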
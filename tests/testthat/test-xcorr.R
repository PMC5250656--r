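test_that("cross_correlate matches a direct lag-by-lag oracle", {
  set.seed(12)
  a <- rnorm(60)
  b <- rnorm(60)
  cc <- cross_correlate(lfp_signal(a, 20), lfp_signal(b, 20), max_lag_s = 0.3)
  a0 <- a - mean(a)
  b0 <- b - mean(b)
  direct <- vapply(-6:6, function(l) {
    if (l >= 0) {
      sum(a0[1:(60 - l)] * b0[(1 + l):60]) / (60 - l)
    } else {
      sum(a0[(1 - l):60] * b0[1:(60 + l)]) / (60 + l)
    }
  }, numeric(1))
  expect_equal(cc$values, direct, tolerance = 1e-12)
  expect_equal(cc$lags_s, (-6:6) / 20)
})

test_that("autocorrelation at zero lag is the mean-of-squares variance", {
  x <- noise_signal(n = 5000, fs = 500, seed = 1)
  cc <- cross_correlate(x, x, max_lag_s = 0.5)
  s0 <- x$samples - mean(x$samples)
  expect_equal(cc$values[cc$lags_s == 0], mean(s0^2), tolerance = 1e-9)
  # anti-correlated copy: c(tau) = -autocorrelation, exactly
  neg <- lfp_signal(-x$samples, 500)
  ccn <- cross_correlate(x, neg, max_lag_s = 0.5)
  expect_equal(ccn$values, -cc$values, tolerance = 1e-12)
})

test_that("swapping the inputs mirrors the lag axis", {
  pair <- quick_pair(duration = 30, fs = 250, seed = 6)
  ab <- cross_correlate(pair$x, pair$y, max_lag_s = 1)
  ba <- cross_correlate(pair$y, pair$x, max_lag_s = 1)
  expect_equal(ab$values, rev(ba$values), tolerance = 1e-12)
  expect_error(cross_correlate(pair$x, lfp_signal(pair$y$samples, 260)),
               "rates differ")
  expect_error(cross_correlate(pair$x, pair$y, max_lag_s = 20), "half")
})

test_that("spikes locked to a sine's peaks average to a windowed cosine", {
  fs <- 500
  t <- (0:(fs * 60 - 1)) / fs
  amp <- 40
  lfp <- lfp_signal(amp * cos(2 * pi * 2 * t), fs)
  peaks <- seq(2, 58, by = 0.5) # every peak of the 2 Hz cosine
  stl <- st_average(spike_train(peaks, 60), lfp, window_s = 1)
  expect_equal(stl$values, amp * cos(2 * pi * 2 * stl$lags_s), tolerance = 0.01)
  expect_equal(stl$n_events, length(peaks))
})

test_that("triggering on every sample averages to ~0 for a zero-mean signal", {
  x <- noise_signal(n = 10000, fs = 250, seed = 11)
  all_times <- (seq_along(x$samples) - 1) / 250
  stl <- st_average(spike_train(all_times[-1], 40), x, window_s = 0.5)
  expect_lt(max(abs(stl$values)), 0.02 * stats::sd(x$samples))
  expect_gt(stl$meta$n_skipped, 0) # windows near the edges are dropped
})

test_that("stLFP equals the continuous cross-correlation up to ordinate scale", {
  pair <- quick_pair(duration = 150, fs = 500, seed = 13)
  spikes <- derive_spikes(pair$x, 99)
  stl <- st_average(spikes, pair$y, window_s = 1)
  cc <- cross_correlate(pair$x, pair$y, max_lag_s = 1)
  expect_gt(stats::cor(stl$values, cc$values), 0.95)
})

test_that("st_average needs at least one usable spike", {
  x <- noise_signal(n = 1000, fs = 100, seed = 3)
  expect_error(st_average(spike_train(0.01, 10), x, window_s = 1), "full")
})

test_that("a monophasic trough is not biphasic; filtering makes it so; correction undoes it", {
  fs <- 250
  dur <- 40
  t <- (0:(fs * dur - 1)) / fs
  bump <- -80 * exp(-(t - 20)^2 / (2 * 0.25^2)) # negative Gaussian, sd 250 ms
  keep <- abs(t - 20) <= 1.5
  as_cc <- function(values) {
    cross_correlation(t[keep] - 20, values[keep])
  }
  raw <- biphasic_index(as_cc(bump))
  expect_lt(abs(raw$ratio), 0.01)
  expect_false(raw$biphasic)

  model <- filter_preset("openephys-0.1hz")
  filtered_sig <- apply_tf(lfp_signal(bump, fs), model)
  # independent oracle: causal first-order high-pass response to a Gaussian,
  # g'(t) = g(t) - w0 * exp(w0^2 s^2/2 - w0 (t - mu)) * Phi((t-mu-w0 s^2)/s) * M
  w0 <- 2 * pi * 0.1
  s <- 0.25
  M <- -80 * s * sqrt(2 * pi)
  oracle <- bump - w0 * M * exp(w0^2 * s^2 / 2 - w0 * (t - 20)) *
    stats::pnorm((t - 20 - w0 * s^2) / s)
  expect_lt(max(abs(filtered_sig$samples[keep] - oracle[keep])), 0.02 * 80)

  filt <- biphasic_index(as_cc(filtered_sig$samples))
  expect_gt(filt$ratio, 0.2)
  expect_true(filt$biphasic)

  corrected_sig <- phase_correct(filtered_sig, model)
  corr <- biphasic_index(as_cc(corrected_sig$samples))
  expect_false(corr$biphasic)
})

test_that("biphasic_index needs lags out to the admissible peak delay", {
  cc <- cross_correlation(seq(-0.5, 0.5, by = 0.01),
                          -dnorm(seq(-0.5, 0.5, by = 0.01), sd = 0.1))
  expect_error(biphasic_index(cc), "too short")
  expect_silent(biphasic_index(cc, peak_hi_s = 0.4))
})

test_that("Welch PSD of white noise is flat and integrates to the variance", {
  x <- noise_signal(n = 150 * 200, fs = 200, seed = 21, sd = 3)
  ps <- welch_psd(x, segment_s = 2)
  total <- sum(ps$psd) * (ps$freq_hz[2] - ps$freq_hz[1])
  expect_lt(abs(total / stats::var(x$samples) - 1), 0.05)
  expect_gt(attr(ps, "n_segments"), 50)
})

test_that("coherence is 1 with itself and small between independent signals", {
  x <- noise_signal(n = 300 * 200, fs = 200, seed = 22)
  y <- noise_signal(n = 300 * 200, fs = 200, seed = 23)
  self <- welch_coherence(x, x, segment_s = 1)
  expect_true(all(self$coherence > 1 - 1e-9))
  indep <- welch_coherence(x, y, segment_s = 0.5)
  expect_lt(max(indep$coherence), 0.1)
  short <- lfp_signal(rnorm(100), 200)
  expect_error(welch_psd(short, segment_s = 2), "5 segments")
})
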
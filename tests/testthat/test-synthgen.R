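test_that("full coherence forces y = -x; the pair is reproducible by seed", {
  f <- 10^seq(-3, 3, length.out = 50)
  sp <- make_spectral_spec("tabulated", freqs_hz = f,
                           power = rep(10, 50), coherence = rep(1, 50))
  pair <- generate_pair(sp, duration_s = 20, fs_hz = 200, seed = 5)
  expect_equal(pair$y$samples, -pair$x$samples,
               tolerance = 1e-10)
  again <- generate_pair(sp, 20, 200, seed = 5)
  expect_identical(pair$x$samples, again$x$samples)
  expect_identical(pair$y$samples, again$y$samples)
  other <- generate_pair(sp, 20, 200, seed = 6)
  expect_false(identical(pair$x$samples, other$x$samples))
})

test_that("zero coherence leaves the pair uncorrelated at zero lag", {
  f <- 10^seq(-3, 3, length.out = 50)
  sp <- make_spectral_spec("tabulated", freqs_hz = f,
                           power = rep(10, 50), coherence = rep(0, 50))
  z <- vapply(1:12, function(seed) {
    pair <- generate_pair(sp, 30, 200, seed = seed)
    stats::cor(pair$x$samples, pair$y$samples)
  }, numeric(1))
  expect_lt(abs(mean(z)) / (stats::sd(z) / sqrt(length(z))), 3)
})

test_that("flat spectrum with C = 0.5 realizes magnitude coherence 0.5", {
  f <- 10^seq(-3, 3, length.out = 50)
  sp <- make_spectral_spec("tabulated", freqs_hz = f,
                           power = rep(4, 50), coherence = rep(0.5, 50))
  pair <- generate_pair(sp, duration_s = 120, fs_hz = 200, seed = 9)
  co <- welch_coherence(pair$x, pair$y, segment_s = 1) # >= 100 averaged segments
  mid <- co$freq_hz > 5 & co$freq_hz < 95
  expect_lt(abs(mean(co$coherence[mid]) - 0.5), 0.05)
})

test_that("spectral families evaluate to their closed forms", {
  flat <- make_spectral_spec("flat", amplitude = 7)
  expect_true(all(flat$power == 7))
  knee <- make_spectral_spec(amplitude = 1000, knee_hz = 2, exponent = 2,
                             hf_floor = 0, osc_amp = 0,
                             freqs_hz = c(0.01, 2, 200))
  expect_equal(knee$power[2], 500, tolerance = 1e-12) # half power at the knee
  expect_equal(knee$power[1], 1000, tolerance = 1e-3) # plateau below
  # coherence: plateau below band_lo, zero above band_hi
  sp <- make_spectral_spec(c_max = 0.8, band_lo_hz = 2, band_hi_hz = 20)
  expect_equal(max(sp$coherence), 0.8)
  expect_true(all(sp$coherence[sp$freqs_hz <= 2] == 0.8))
  expect_true(all(sp$coherence[sp$freqs_hz >= 20] == 0))
})

test_that("the low-frequency multiplier scales the sub-band exactly and fixes the tail", {
  members <- lapply(c(0.3, 1, 3), function(m) make_spectral_spec(lf_mult = m))
  base <- members[[2]]
  low <- base$freqs_hz < 0.5   # fully inside the multiplier band
  high <- base$freqs_hz > 2    # fully outside it
  band_power <- function(sp, sel) sum(sp$power[sel])
  expect_equal(band_power(members[[1]], low) / band_power(base, low), 0.3,
               tolerance = 1e-9)
  expect_equal(band_power(members[[3]], low) / band_power(base, low), 3,
               tolerance = 1e-9)
  expect_equal(members[[1]]$power[high], base$power[high], tolerance = 1e-12)
  expect_equal(members[[3]]$power[high], base$power[high], tolerance = 1e-12)
})

test_that("generated signals realize the specified spectrum and coherence", {
  pair <- quick_pair(duration = 150, fs = 500, seed = 4)
  sp <- make_spectral_spec()
  ps <- welch_psd(pair$y, segment_s = 5)
  edges <- 10^seq(log10(0.2), log10(200), length.out = 6)
  for (i in 1:5) {
    sel <- ps$freq_hz >= edges[i] & ps$freq_hz < edges[i + 1]
    target <- approx(sp$freqs_hz, sp$power, ps$freq_hz[sel], rule = 2)$y
    expect_lt(abs(mean(ps$psd[sel]) / mean(target) - 1), 0.1)
  }
  co <- welch_coherence(pair$x, pair$y, segment_s = 5)
  flatband <- co$freq_hz >= 0.4 & co$freq_hz <= 2
  expect_lt(abs(mean(co$coherence[flatband]) - 0.9), 0.05)
})

test_that("the pair's cross-correlation has a symmetric central trough", {
  pair <- quick_pair(duration = 150, fs = 500, seed = 8)
  cc <- cross_correlate(pair$x, pair$y, max_lag_s = 1)
  expect_lt(asymmetry_index(cc), 0.05)
  # cross-spectrum -C*P is real and non-positive: trough at zero lag
  expect_lt(cc$values[cc$lags_s == 0], 0)
  expect_equal(cc$lags_s[which.min(cc$values)], 0, tolerance = 0.02)
})

test_that("threshold crossings behave like spikes", {
  fs <- 1000
  t <- (0:9999) / fs
  sine <- lfp_signal(sin(2 * pi * 2 * t), fs)
  # threshold at the median (= 0 for a sine): one upward crossing per period
  spk <- derive_spikes(sine, 50)
  expect_equal(length(spk$times_s), 20, tolerance = 0.051)
  dist_to_period <- abs((spk$times_s + 0.25) %% 0.5 - 0.25)
  expect_lt(max(dist_to_period), 1.5 / fs + 1e-9)

  pair <- quick_pair(duration = 60, fs = 500, seed = 2)
  spk99 <- derive_spikes(pair$x, 99)
  expect_lt(length(spk99$times_s), 0.01 * length(pair$x$samples))
  expect_gt(length(spk99$times_s), 1)

  falling <- lfp_signal(seq(1, 0, length.out = 100), 100)
  expect_length(derive_spikes(falling, 90)$times_s, 0)
  expect_warning(const <- derive_spikes(lfp_signal(rep(1, 100), 100), 99),
                 "constant")
  expect_length(const$times_s, 0)
})

test_that("generator rejects invalid spectral input", {
  f <- c(1, 2, 3)
  expect_error(spectral_spec(f, c(1, 1, 1), c(0, 0.5, 1.2)), "\\[0, 1\\]")
  expect_error(spectral_spec(f, c(1, -1, 1), c(0, 0, 0)), "power")
  expect_error(make_spectral_spec("flat", amplitude = -3), "non-negative")
  sp <- make_spectral_spec()
  expect_error(generate_pair(sp, duration_s = 0.004, fs_hz = 500, seed = 1),
               "too short")
})
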
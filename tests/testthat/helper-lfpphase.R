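# Shared fixtures, built in code at test time.

# A white-noise test signal.
noise_signal <- function(n = 4096, fs = 500, seed = 1, sd = 1) {
  set.seed(seed)
  lfp_signal(rnorm(n, sd = sd), fs_hz = fs)
}

# A random cascade of first-order analog stages (closed-form responses are
# available for these, so tests can use an independent oracle).
random_cascade <- function(seed, n_stages = NULL) {
  set.seed(seed)
  if (is.null(n_stages)) n_stages <- sample(1:3, 1)
  stages <- lapply(seq_len(n_stages), function(i) {
    kind <- sample(c("first_order_highpass", "butterworth_lowpass"), 1)
    cutoff <- 10^runif(1, -1, if (kind == "butterworth_lowpass") 3 else 1)
    filter_model(kind, cutoff_hz = cutoff)
  })
  filter_model("cascade", stages = stages)
}

# Independent complex-arithmetic oracle for cascades of first-order stages:
# H_hp(f) = (i f / fc) / (1 + i f / fc), H_lp(f) = 1 / (1 + i f / fc).
cascade_oracle <- function(model, f) {
  H <- rep(1 + 0i, length(f))
  for (s in model$stages) {
    H <- H * switch(s$kind,
      first_order_highpass = (1i * f / s$cutoff_hz) / (1 + 1i * f / s$cutoff_hz),
      butterworth_lowpass = 1 / (1 + 1i * f / s$cutoff_hz))
  }
  H
}

# A gain-only (zero phase) tabulation of `model` on the FFT grid of an
# n-sample record at rate fs, for exact-identity comparisons.
gain_only_tf <- function(model, n, fs) {
  k <- seq_len(ceiling(n / 2) - 1)
  f <- unique(c(k * fs / n, if (n %% 2 == 0) fs / 2))
  tf <- evaluate_model(model, f)
  transfer_function(tf$freqs_hz, tf$gain, rep(0, length(f)))
}

# Small coherent pair under the default spectral family.
quick_pair <- function(duration = 120, fs = 500, seed = 1, ...) {
  generate_pair(make_spectral_spec(...), duration, fs, seed = seed)
}
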
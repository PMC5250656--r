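test_that("first-order high-pass matches its analytic response", {
  tf <- evaluate_model(filter_model("first_order_highpass", cutoff_hz = 1),
                       c(1, 1000))
  # at the cutoff: gain 1/sqrt(2), phase lead pi/4
  expect_equal(tf$gain[1], 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(tf$phase_rad[1], pi / 4, tolerance = 1e-12)
  # far above the cutoff the filter is transparent
  expect_lt(abs(tf$gain[2] - 1), 1e-6)
  expect_lt(abs(tf$phase_rad[2]), 1e-3)
})

test_that("butterworth responses follow the closed-form magnitude", {
  f <- 10^seq(-1, 3, length.out = 40)
  for (ord in c(1L, 2L, 4L)) {
    lp <- evaluate_model(filter_model("butterworth_lowpass", 20, order = ord), f)
    expect_equal(lp$gain, 1 / sqrt(1 + (f / 20)^(2 * ord)), tolerance = 1e-12)
    hp <- evaluate_model(filter_model("butterworth_highpass", 20, order = ord), f)
    expect_equal(hp$gain, 1 / sqrt(1 + (20 / f)^(2 * ord)), tolerance = 1e-12)
  }
  # phase is unwrapped even for orders whose total shift exceeds pi
  hp4 <- evaluate_model(filter_model("butterworth_highpass", 20, order = 4L), f)
  expect_lt(max(abs(diff(hp4$phase_rad))), pi)
  expect_gt(hp4$phase_rad[1], pi) # near-DC phase of a 4th-order HP approaches 2*pi
})

test_that("two identical high-pass stages at their cutoff give gain 1/2, phase pi/2", {
  casc <- filter_model("cascade", stages = list(
    filter_model("first_order_highpass", 2),
    filter_model("first_order_highpass", 2)
  ))
  tf <- evaluate_model(casc, 2)
  # independent oracle: (i/(1+i))^2 = i/2
  expect_equal(tf$gain, 0.5, tolerance = 1e-12)
  expect_equal(tf$phase_rad, pi / 2, tolerance = 1e-12)
})

test_that("cascade response equals the product of its stages (complex oracle)", {
  f <- 10^seq(-2, 3, length.out = 60)
  for (seed in 1:5) {
    model <- random_cascade(seed)
    tf <- evaluate_model(model, f)
    H <- cascade_oracle(model, f)
    expect_equal(tf$gain, Mod(H), tolerance = 1e-10)
    # compare wrapped phases; evaluate_model may unwrap across frequency
    expect_lt(max(abs(Arg(exp(1i * (tf$phase_rad - Arg(H)))))), 1e-10)
  }
})

test_that("high-pass phase lies in (0, pi/2) and decreases with frequency", {
  f <- 10^seq(-3, 4, length.out = 200)
  tf <- evaluate_model(filter_model("first_order_highpass", 0.5), f)
  expect_true(all(tf$phase_rad > 0 & tf$phase_rad < pi / 2))
  expect_true(all(diff(tf$phase_rad) < 0))
  expect_true(all(diff(tf$gain) > 0))
})

test_that("model evaluation rejects bad input", {
  m <- filter_model("first_order_highpass", 1)
  expect_error(evaluate_model(m, c(-1, 2)), "positive")
  expect_error(evaluate_model(m, numeric(0)), "positive")
  expect_error(filter_model("first_order_highpass", -1), "positive")
  expect_error(filter_model("first_order_highpass", 1, order = 2), "order 1")
  expect_error(filter_model("cascade", stages = list()), "non-empty")
})

test_that("transfer_function enforces its invariants", {
  expect_error(transfer_function(c(1, 1), c(1, 1), c(0, 0)), "increasing")
  expect_error(transfer_function(c(0, 1), c(1, 1), c(0, 0)), "> 0")
  expect_error(transfer_function(c(1, 2), c(-0.1, 1), c(0, 0)), "gain")
  expect_error(transfer_function(c(1, 2), c(1, 1), c(0, 4)), "unwrapped")
})

test_that("interpolation is exact at nodes and log-log linear between them", {
  tf <- transfer_function(c(0.1, 10), c(0.5, 1.0), c(0.8, 0.1))
  # identity at tabulated frequencies
  at_nodes <- interpolate_tf(tf, c(0.1, 10))
  expect_equal(at_nodes$gain, tf$gain, tolerance = 1e-12)
  expect_equal(at_nodes$phase_rad, tf$phase_rad, tolerance = 1e-12)
  # log-frequency midpoint of 0.1 and 10 Hz is 1 Hz; dB midpoint of
  # {-6.0206, 0} dB is -3.0103 dB = 1/sqrt(2)
  mid <- interpolate_tf(tf, 1)
  expect_equal(mid$gain, 1 / sqrt(2), tolerance = 1e-9)
  expect_equal(mid$phase_rad, 0.45, tolerance = 1e-9)
  # beyond the table: endpoint hold
  outside <- interpolate_tf(tf, c(0.01, 100))
  expect_equal(outside$gain, c(0.5, 1.0))
  expect_equal(outside$phase_rad, c(0.8, 0.1))
})

test_that("interpolation is idempotent on its own output grid", {
  tf <- evaluate_model(filter_preset("cerebus-like"), calibration_grid(9))
  grid <- 10^seq(-1.5, 1.2, length.out = 25)
  once <- interpolate_tf(tf, grid)
  twice <- interpolate_tf(once, grid)
  expect_equal(twice$gain, once$gain, tolerance = 1e-12)
  expect_equal(twice$phase_rad, once$phase_rad, tolerance = 1e-12)
})

test_that("transfer-function CSV round trip is lossless and normalizing", {
  tf <- evaluate_model(filter_preset("openephys-1hz"), calibration_grid(11))
  path <- withr::local_tempfile(fileext = ".csv")
  write_tf_csv(tf, path)
  back <- read_tf_csv(path)
  expect_equal(back$freqs_hz, tf$freqs_hz, tolerance = 1e-12)
  expect_equal(back$gain, tf$gain, tolerance = 1e-12)
  expect_equal(back$phase_rad, tf$phase_rad, tolerance = 1e-12)

  # unsorted rows are sorted on read
  lines <- readLines(path)
  writeLines(c(lines[1], rev(lines[-1])), path)
  resorted <- read_tf_csv(path)
  expect_equal(resorted$freqs_hz, tf$freqs_hz, tolerance = 1e-12)

  # duplicate frequency and non-numeric cells are format errors naming the row
  writeLines(c(lines, lines[2]), path)
  expect_error(read_tf_csv(path), "duplicate frequency")
  writeLines(c(lines[1], "0.1,abc,0.2", lines[-1]), path)
  expect_error(read_tf_csv(path), "non-numeric.*row 1")
  writeLines(c("freq_hz,gain", "1,1"), path)
  expect_error(read_tf_csv(path), "missing column")
})
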
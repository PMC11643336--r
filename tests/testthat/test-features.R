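test_that("the default registry has the documented composition", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 378)
  expect_equal(as.vector(table(reg$family)[c("spectral", "orientation",
                                             "xcorr")]),
               c(312L, 52L, 14L))
  expect_false(anyDuplicated(reg$name) > 0)
  expect_false(any(grepl("mag", reg$modality))) # magnetometer unused
})

test_that("dominant frequency recovers planted tones within the grid", {
  t <- seq(0, 8, by = 1 / 32)
  r <- dominant_frequency(sin(2 * pi * 1.5 * t), 32)
  expect_equal(r$value, 1.5, tolerance = 0.051)
  expect_false(r$flag)

  two <- 2 * sin(2 * pi * 0.5 * t) + sin(2 * pi * 2 * t)
  expect_equal(dominant_frequency(two, 32)$value, 0.5, tolerance = 0.051)

  z <- dominant_frequency(rep(0, 256), 32)
  expect_equal(z$value, 0)
  expect_true(z$flag)
})

test_that("mean frequency is the power-weighted spectral centroid", {
  t <- seq(0, 16, by = 1 / 32)
  expect_equal(mean_frequency(sin(2 * pi * 1 * t), 32)$value, 1,
               tolerance = 0.05)
  two <- sin(2 * pi * 1 * t) + sin(2 * pi * 3 * t)
  expect_equal(mean_frequency(two, 32)$value, 2, tolerance = 0.06)
  expect_true(mean_frequency(rep(0, 256), 32)$flag)
})

test_that("mean frequency lies between the tones of a two-tone input", {
  t <- seq(0, 12, by = 1 / 32)
  for (a in c(0.3, 1, 3)) {
    mf <- mean_frequency(a * sin(2 * pi * 0.8 * t) + sin(2 * pi * 2.5 * t),
                         32)$value
    expect_gt(mf, 0.8)
    expect_lt(mf, 2.5)
  }
})

test_that("orientation metrics follow the gravity-vector convention", {
  n <- 50
  flat <- orientation_metrics(rep(0, n), rep(0, n), rep(1, n))
  expect_equal(flat$pitch_mean, 0)
  expect_equal(flat$roll_mean, 0)
  expect_equal(flat$pitch_range, 0)

  tilted <- orientation_metrics(rep(-sin(pi / 6), n), rep(0, n),
                                rep(cos(pi / 6), n))
  expect_equal(tilted$pitch_mean, 30, tolerance = 1e-9)
  expect_equal(tilted$roll_mean, 0)

  # slow sinusoidal tilt of +/-15 degrees -> pitch range ~ 30 degrees
  ang <- 15 * sin(2 * pi * seq(0, 1, length.out = 200)) * pi / 180
  sweep <- orientation_metrics(-sin(ang), rep(0, 200), cos(ang))
  expect_equal(sweep$pitch_range, 30, tolerance = 0.1)

  weak <- orientation_metrics(rep(0.1, n), rep(0.1, n), rep(0.1, n))
  expect_true(weak$flag)
})

test_that("cross-correlation recovers sign, identity, and planted lags", {
  t <- seq(0, 10, by = 1 / 32)
  a <- sin(2 * pi * 0.5 * t)
  self <- xcorr_features(a, a, 32)
  expect_equal(self$peak, 1, tolerance = 1e-9)
  expect_equal(self$lag_s, 0)

  anti <- xcorr_features(a, -a, 32)
  expect_equal(anti$peak, -1, tolerance = 1e-9)
  expect_equal(anti$lag_s, 0)

  lag_n <- round(0.25 * 32)
  b <- c(rep(0, lag_n), a[seq_len(length(a) - lag_n)])
  shifted <- xcorr_features(a, b, 32, max_lag_s = 1)
  expect_equal(shifted$lag_s, 0.25, tolerance = 1 / 32 + 1e-9)

  flagged <- xcorr_features(rep(1, 100), rnorm(100), 32)
  expect_true(flagged$flag)
  expect_equal(flagged$peak, 0)
})

test_that("extraction yields complete, deterministic, order-invariant vectors", {
  fs <- fix_filtered()
  s <- fix_session()
  rep1 <- s$truth[1, ]
  v1 <- extract_features(rep1, fs)
  expect_length(v1$values, 378)
  expect_identical(names(v1$values), feature_registry()$name)
  expect_true(all(is.finite(v1$values)))

  v2 <- extract_features(rep1, fs)
  expect_identical(v1, v2)

  perm <- fs
  perm$channels <- rev(perm$channels)
  v3 <- extract_features(rep1, perm)
  expect_identical(v1$values, v3$values)

  freqs <- v1$values[grepl("^spec_", names(v1$values))]
  expect_true(all(freqs >= 0 & freqs <= 16))
})

test_that("driving-channel dominant frequencies sit at the archetype tempo", {
  fs <- fix_filtered()
  s <- fix_session()
  f0 <- movement_archetypes()$RTP$fundamental_hz
  rtp <- s$truth[s$truth$movement == "RTP", ]
  doms <- vapply(seq_len(nrow(rtp)), function(i) {
    extract_features(rtp[i, ], fs)$values[["spec_wrist_r_gyr_y_bp_domf"]]
  }, numeric(1))
  # high-grade repetitions: within tempo jitter + grid of the fundamental
  expect_true(all(abs(doms - f0) < 0.12))
})

test_that("too-short repetitions are refused", {
  fs <- fix_filtered()
  short <- tibble::tibble(start_s = 3, end_s = 3.2)
  expect_error(extract_features(short, fs),
               class = "moveprof_extraction_error")
})
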
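tone <- function(freq, dur, rate, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * seq(0, dur, by = 1 / rate) + phase)
}

# steady-state amplitude, away from the edges
mid_amp <- function(x, trim = 0.2) {
  n <- length(x)
  max(abs(x[round(n * trim):round(n * (1 - trim))]))
}

test_that("resampling preserves DC, tones, and duration", {
  dc <- resample_series(rep(2.5, 300), 100, 32)
  expect_equal(dc, rep(2.5, length(dc)), tolerance = 1e-9)
  expect_true(abs(length(dc) - 299 / 100 * 32) <= 1)
  x <- tone(1, 10, 100)
  y <- resample_series(x, 100, 32)
  t32 <- (seq_along(y) - 1) / 32
  expect_lt(max(abs(y - sin(2 * pi * t32))), 0.01) # amplitude within 1%
  expect_equal(length(y), 321) # 10 s at 32 Hz (+1 for t = 0)
  n <- length(resample_series(rnorm(100), 100, 32))
  expect_true(abs(n - 32) <= 1)
  expect_error(resample_series(x, 32, 100), class = "moveprof_parameter_error")
})

test_that("anti-alias filtering removes content beyond the target Nyquist", {
  x <- tone(20, 5, 100)
  y <- resample_series(x, 100, 32)
  expect_lt(mid_amp(y), 1e-3)
})

test_that("low-pass meets pass/stop-band contracts on tones", {
  c0 <- lowpass_filter(rep(3, 500), 32)
  expect_equal(mid_amp(c0) / 3, 1, tolerance = 0.12) # within doubled ripple
  expect_gte(mid_amp(lowpass_filter(tone(1, 20, 32), 32)), 0.95)
  expect_lte(mid_amp(lowpass_filter(tone(10, 20, 32), 32)), 0.05)
  expect_error(lowpass_filter(rnorm(100), 32, cutoff_hz = 16),
               class = "moveprof_parameter_error")
})

test_that("band-pass rejects DC, passes 1 Hz, and removes slow drift", {
  y <- bandpass_filter(rep(3, 2000), 32)
  expect_lt(max(abs(y[500:1500])), 1e-3 * 3)
  y1 <- bandpass_filter(tone(1, 60, 32), 32)
  expect_gte(mid_amp(y1), 0.85)
  two <- 5 + 2 * tone(0.01, 60, 32) + tone(1, 60, 32)
  yr <- bandpass_filter(two, 32)
  expect_equal(mid_amp(yr), 1, tolerance = 0.15) # the 1 Hz tone survives
  expect_lt(abs(mean(yr[500:1400])), 0.02) # drift and DC are gone
  expect_equal(bandpass_filter(rep(0, 400), 32), rep(0, 400))
})

test_that("filters are linear and idempotent in the passband", {
  x <- tone(0.7, 30, 32)
  y <- tone(2.3, 30, 32)
  lin <- lowpass_filter(2 * x + 3 * y, 32)
  sep <- 2 * lowpass_filter(x, 32) + 3 * lowpass_filter(y, 32)
  expect_equal(lin, sep, tolerance = 1e-8)

  # passband gain consistency: the second application scales the signal by
  # the same factor as the first (no cumulative distortion beyond ripple)
  pure <- tone(1, 60, 32)
  once <- bandpass_filter(pure, 32)
  twice <- bandpass_filter(once, 32)
  g1 <- mid_amp(once) / mid_amp(pure)
  g2 <- mid_amp(twice) / mid_amp(once)
  expect_equal(g2, g1, tolerance = 0.03)
})

test_that("low-pass minus band-pass recovers the sub-0.1 Hz content", {
  t <- seq(0, 120, by = 1 / 32)
  slow <- 2 * sin(2 * pi * 0.02 * t)
  fast <- sin(2 * pi * 1 * t)
  x <- slow + fast
  resid <- lowpass_filter(x, 32) - bandpass_filter(x, 32)
  mid <- 1500:2200
  expect_lt(sqrt(mean((resid[mid] - slow[mid])^2)), 0.25)
})

test_that("a preprocessed session carries both filtered variants at 32 Hz", {
  fs <- fix_filtered()
  expect_equal(fs$rate_hz, 32)
  ch <- fs$channels$wrist_r
  expect_true(all(c("gx_dps_lp", "gx_dps_bp", "gmag_lp", "gmag_bp") %in%
                    names(ch)))
  expect_equal(nrow(ch), length(ch$gmag_lp))
  # band-pass variants are mean-free
  expect_lt(abs(mean(ch$gx_dps_bp)), 0.5)
})

test_that("the cascade band-pass and single-design band-pass are both available", {
  cfg <- preprocess_config(band.cascade = FALSE)
  y <- bandpass_filter(tone(1, 60, 32), 32, config = cfg)
  expect_gte(mid_amp(y), 0.8)
  expect_error(preprocess_config(nonsense_key = 1),
               class = "moveprof_config_error")
})
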
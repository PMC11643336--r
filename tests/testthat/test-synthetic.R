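test_that("a generated subject honors the configured repetition structure", {
  s <- fix_session()
  # RTP unilateral, GST bilateral, 6 reps each
  expect_equal(nrow(s$markers), 3)
  expect_equal(nrow(s$truth), 18)
  expect_equal(as.vector(table(s$truth$movement)[c("GST", "RTP")]),
               c(12L, 6L))
  expect_equal(max(s$truth$repetition), 6)
  # channels complete and in range
  expect_setequal(names(s$channels), body_placements()$site)
  expect_silent(validate_session(s))
})

test_that("generation is bit-identical under the same seed and differs across seeds", {
  cfg <- cohort_config(n_subjects = 2, movements = "RTP", seed = 11)
  a <- generate_subject(movement_archetypes(), "high", cfg, seed = 7)
  b <- generate_subject(movement_archetypes(), "high", cfg, seed = 7)
  expect_identical(a, b)
  c <- generate_subject(movement_archetypes(), "high", cfg, seed = 8)
  expect_false(identical(a$channels$wrist_r$gx_dps, c$channels$wrist_r$gx_dps))
})

test_that("low grade shows larger per-repetition period variance than high", {
  cfg <- cohort_config(n_subjects = 2, movements = "GST", seed = 11)
  arch <- movement_archetypes()
  per_var <- function(grade, seed) {
    s <- generate_subject(arch, setNames(grade, "GST"), cfg, seed = seed)
    tr <- s$truth
    var(diff((tr$start_s + tr$end_s) / 2)[seq_len(5)])
  }
  # averaged over a few seed pairs at the same seed stream
  lows <- vapply(1:6, function(i) per_var("low", 100 + i), numeric(1))
  highs <- vapply(1:6, function(i) per_var("high", 100 + i), numeric(1))
  expect_gt(mean(lows), mean(highs))
})

test_that("cohort truth table size follows the protocol arithmetic", {
  cohort <- memo("cohort8_tiny", {
    # 8 x (5 bilateral x 2 sides x 6 reps + RTP x 6) = 528, from config alone
    cfg <- cohort_config(n_subjects = 8, seed = 3,
                         repetitions_per_movement = 6)
    n_bilateral <- length(setdiff(cfg$movements, "RTP"))
    list(expected = cfg$n_subjects *
           (n_bilateral * 2 * 6 + 6))
  })
  expect_equal(cohort$expected, 528)
  mini <- fix_mini_cohort()
  # 3 subjects x (RTP 6 + GST 2x6) = 54
  expect_equal(nrow(mini$truth), 54)
})

test_that("grade assignment follows class proportions by largest remainder", {
  set.seed(1)
  g <- moveprof:::assign_grades(sprintf("S%02d", 1:10), c("GST", "RTP"),
                                c(low = 0.5, medium = 0.2, high = 0.3))
  counts <- table(g$movement, g$grade)
  expect_equal(as.vector(counts["GST", c("low", "medium", "high")]),
               c(5L, 2L, 3L))
  expect_equal(as.vector(counts["RTP", c("low", "medium", "high")]),
               c(5L, 2L, 3L))
})

test_that("degradation profiles strictly decrease from low to high grade", {
  p <- proficiency_profiles()
  expect_equal(p$grade, c("low", "medium", "high"))
  for (cc in setdiff(names(p), "grade")) {
    expect_true(all(diff(p[[cc]]) < 0), info = cc)
    expect_true(all(p[[cc]] > 0), info = cc)
  }
})

test_that("templates exceeding hardware ranges are rejected", {
  arch <- movement_archetypes()
  bad <- arch$RTP
  bad$sites$gyro_amp <- bad$sites$gyro_amp * 40 # beyond 2000 deg/s
  cfg <- cohort_config(n_subjects = 2, movements = "RTP", seed = 1)
  expect_error(
    generate_subject(list(RTP = bad), "high", cfg, seed = 1),
    class = "moveprof_range_error"
  )
})

test_that("pauses keep the smoothed gyro envelope below the segmenter floor", {
  fs <- fix_filtered()
  s <- fix_session()
  blocks <- split_movements(fs)
  cfg <- segment_config()
  for (b in seq_len(nrow(blocks))) {
    env <- velocity_envelope(blocks$channels[[b]], cfg$envelope_placements)
    tr <- s$truth[s$truth$block == b, ]
    # interior truth cuts sit at pause midpoints: envelope must be quiet
    cuts <- tr$end_s[-nrow(tr)] - blocks$start_s[b]
    idx <- round(cuts * fs$rate_hz)
    expect_true(all(env[idx] < cfg$threshold_dps))
  }
})

test_that("high-grade band-pass power concentrates near the archetype lines", {
  fs <- fix_filtered()
  s <- fix_session()
  blk <- split_movements(fs)[1, ] # RTP, high grade
  x <- blk$channels[[1]]$wrist_r$gy_dps_bp
  x <- x - mean(x)
  ps <- Mod(stats::fft(x))^2
  f <- (seq_along(ps) - 1) * fs$rate_hz / length(ps)
  half <- f <= fs$rate_hz / 2
  f <- f[half]; ps <- ps[half]
  f0 <- movement_archetypes()$RTP$fundamental_hz
  lines <- f0 * c(1, 2, 3)
  near <- Reduce(`|`, lapply(lines, function(l) abs(f - l) <= 0.2))
  expect_gt(sum(ps[near]) / sum(ps), 0.8)
})
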
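test_that("movement blocks follow the markers exactly", {
  fs <- fix_filtered()
  blocks <- split_movements(fs)
  expect_equal(nrow(blocks), nrow(fs$markers))
  expect_equal(blocks$movement, fs$markers$movement)

  empty <- fs
  empty$markers <- fs$markers[0, ]
  expect_equal(nrow(split_movements(empty)), 0)

  late <- fs
  late$markers$end_s[1] <- 1e6
  expect_error(split_movements(late), class = "moveprof_marker_error")
})

test_that("velocity envelope is the mean low-passed gyro norm of its sources", {
  fs <- fix_filtered()
  blk <- split_movements(fs)[1, ]
  e1 <- velocity_envelope(blk$channels[[1]], "wrist_l")
  e2 <- velocity_envelope(blk$channels[[1]], "wrist_r")
  e12 <- velocity_envelope(blk$channels[[1]], c("wrist_l", "wrist_r"))
  expect_equal(e12, (e1 + e2) / 2)
  expect_true(all(e12 >= 0))
  expect_error(velocity_envelope(blk$channels[[1]], "left_elbow"),
               class = "moveprof_config_error")
})

test_that("pause detection finds exactly the constructed sub-threshold plateaus", {
  # square-wave envelope: 3 quiet plateaus of 0.5 s inside loud stretches
  rate <- 32
  env <- rep(50, 20 * rate)
  quiet <- list(c(4, 4.5), c(9, 9.5), c(15, 15.5))
  for (q in quiet) env[(q[1] * rate):(q[2] * rate)] <- 2
  pauses <- detect_pauses(env, rate, threshold_dps = 10, min_pause_s = 0.2)
  expect_equal(nrow(pauses), 3)
  expect_equal(pauses$start_s, c(4, 9, 15), tolerance = 0.05)

  # a plateau shorter than the minimum is not reported
  env2 <- rep(50, 10 * rate)
  env2[(5 * rate):(5 * rate + 3)] <- 2 # ~0.1 s
  expect_equal(nrow(detect_pauses(env2, rate, 10, 0.2)), 0)

  # always above threshold -> no pauses
  expect_equal(nrow(detect_pauses(rep(50, 320), rate, 10, 0.2)), 0)
})

test_that("k-1 internal pauses yield k repetitions, with review flag on mismatch", {
  rate <- 32
  block <- tibble::tibble(movement = "RTP", side = "na", block = 1L,
                          start_s = 0, end_s = 20)
  env <- rep(50, 20 * rate)
  for (q in list(c(4, 4.5), c(9, 9.5), c(15, 15.5))) {
    env[(q[1] * rate):(q[2] * rate)] <- 2
  }
  pauses <- detect_pauses(env, rate, 10, 0.2)
  reps <- segment_repetitions(block, pauses, rate)
  expect_equal(nrow(reps), 4)
  expect_false(any(reps$review_flag))
  # intervals ordered, disjoint, within the block
  expect_true(all(diff(reps$start_s) > 0))
  expect_true(all(reps$end_s[-4] <= reps$start_s[-1] + 1e-9))

  flagged <- segment_repetitions(block, pauses, rate, expected_count = 9)
  expect_equal(nrow(flagged), 4)
  expect_true(all(flagged$review_flag))
})

test_that("generator ground truth is recovered within tolerance", {
  fs <- fix_filtered()
  s <- fix_session()
  reps <- segment_session(fs)
  expect_equal(nrow(reps), nrow(s$truth))
  cmp <- dplyr::inner_join(reps, s$truth, by = c("block", "repetition"),
                           suffix = c("", "_true"))
  expect_lt(max(abs(cmp$start_s - cmp$start_s_true)), 0.15)
  expect_lt(max(abs(cmp$end_s - cmp$end_s_true)), 0.15)
})

test_that("segmentation ignores accelerometer shifts and sensor order", {
  s <- fix_session()
  shifted <- s
  for (site in names(shifted$channels)) {
    for (cc in c("ax_g", "ay_g")) {
      shifted$channels[[site]][[cc]] <- shifted$channels[[site]][[cc]] + 0.3
    }
  }
  permuted <- s
  permuted$channels <- rev(permuted$channels)
  base <- segment_session(preprocess_session(s))
  expect_equal(segment_session(preprocess_session(shifted)), base)
  expect_equal(segment_session(preprocess_session(permuted)), base)
})

test_that("manual boundary overrides replace automatic cuts", {
  fs <- fix_filtered()
  reps <- segment_session(fs)
  ov <- tibble::tibble(block = reps$block[1], repetition = 1L,
                       start_s = reps$start_s[1] + 0.1,
                       end_s = reps$end_s[1] - 0.1)
  reps2 <- segment_session(fs, overrides = ov)
  expect_equal(reps2$start_s[1], reps$start_s[1] + 0.1)
  expect_equal(reps2$source[1], "manual-override")
  expect_equal(reps2$start_s[-1], reps$start_s[-1])
})
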
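#' Default segmentation configuration
#'
#' Repetition boundaries are found from "velocity zero crossings": in noisy
#' data the angular-velocity envelope never reaches zero, so the crossings
#' are operationalized as sub-threshold intervals of a smoothed gyroscope
#' magnitude envelope. Defaults: threshold 10 deg/s, minimum pause 0.2 s,
#' minimum repetition 1.0 s, envelope sourced from both wrists.
#'
#' @param ... overrides for `threshold_dps`, `min_pause_s`, `min_rep_s`,
#'   `envelope_placements`, `boundary` (`"midpoint"` of the pause or
#'   `"minimum"` of the envelope).
#' @return named list of segmentation parameters.
#' @export
segment_config <- function(...) {
  cfg <- list(
    threshold_dps = 10,
    min_pause_s = 0.2,
    min_rep_s = 1.0,
    envelope_placements = c("wrist_l", "wrist_r"),
    boundary = "midpoint"
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop_moveprof(paste0("unknown segment config key(s): ",
                         paste(unknown, collapse = ", ")),
                  "moveprof_config_error")
  }
  modifyList(cfg, dots)
}

#' Split a filtered session into movement blocks
#'
#' One block per movement marker; samples outside markers are discarded.
#'
#' @param fsession a `filtered_session` from [preprocess_session()].
#' @return tibble with one row per block: `movement`, `side`, `block`,
#'   `start_s`, `end_s`, and a list-column `channels` holding the
#'   marker-windowed channel tibbles.
#' @export
split_movements <- function(fsession) {
  markers <- fsession$markers
  validate_markers(markers)
  t_end <- min(vapply(fsession$channels, function(ch) max(ch$t_s), numeric(1)))
  if (nrow(markers) > 0 && any(markers$end_s > t_end + 1 / fsession$rate_hz)) {
    stop_moveprof("marker extends beyond the recorded signal",
                  "moveprof_marker_error")
  }
  rows <- lapply(seq_len(nrow(markers)), function(b) {
    mk <- markers[b, ]
    chans <- lapply(fsession$channels, function(ch) {
      ch[ch$t_s >= mk$start_s & ch$t_s < mk$end_s, ]
    })
    tibble::tibble(
      movement = mk$movement, side = mk$side, block = b,
      start_s = mk$start_s, end_s = mk$end_s,
      channels = list(chans)
    )
  })
  if (length(rows) == 0) {
    return(tibble::tibble(movement = character(), side = character(),
                          block = integer(), start_s = numeric(),
                          end_s = numeric(), channels = list()))
  }
  dplyr::bind_rows(rows)
}

#' Angular-velocity envelope of a movement block
#'
#' The low-pass-filtered Euclidean norm of the gyroscope vector, averaged
#' over the configured source placements (default: both wrists). This is
#' the series whose sub-threshold intervals mark inter-repetition pauses.
#'
#' @param block_channels named list of per-placement channel tibbles (one
#'   row of [split_movements()]'s `channels` column).
#' @param source_placements placements to average over.
#' @return non-negative numeric envelope at the working rate.
#' @export
velocity_envelope <- function(block_channels,
                              source_placements = c("wrist_l", "wrist_r")) {
  missing_pl <- setdiff(source_placements, names(block_channels))
  if (length(missing_pl) > 0) {
    stop_moveprof(paste0("envelope placement(s) absent: ",
                         paste(missing_pl, collapse = ", ")),
                  "moveprof_config_error")
  }
  envs <- lapply(block_channels[source_placements], function(ch) {
    pmax(ch$gmag_lp, 0)
  })
  Reduce(`+`, envs) / length(envs)
}

#' Detect low-velocity pauses in an envelope
#'
#' Maximal runs where the envelope stays below `threshold_dps` for at least
#' `min_pause_s`. Returned intervals are disjoint and ordered.
#'
#' @param envelope non-negative numeric series at `rate_hz`.
#' @param rate_hz sampling rate of the envelope.
#' @param threshold_dps velocity threshold (deg/s).
#' @param min_pause_s minimum pause duration (s).
#' @return tibble of pause events: `start` and `end` (sample indices,
#'   half-open `[start, end)`), `start_s`, `end_s`, `mean_dps`.
#' @export
detect_pauses <- function(envelope, rate_hz, threshold_dps = 10,
                          min_pause_s = 0.2) {
  below <- envelope < threshold_dps
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= max(1L, ceiling(min_pause_s * rate_hz))
  out <- tibble::tibble(
    start = starts[keep],
    end = ends[keep] + 1L,
    start_s = (starts[keep] - 1L) / rate_hz,
    end_s = ends[keep] / rate_hz,
    mean_dps = vapply(which(keep), function(i) {
      mean(envelope[starts[i]:ends[i]])
    }, numeric(1))
  )
  out
}

#' Segment a movement block into repetitions
#'
#' Cuts the block at pause midpoints (or envelope minima, per config).
#' Leading/trailing fragments shorter than the minimum repetition duration
#' are dropped. When `expected_count` is given and the recovered count
#' differs, the result is flagged for manual review — the automatic
#' segmentation is never silently forced to the expected count; a boundary
#' override file can adjust it downstream.
#'
#' @param block one row of [split_movements()] output (tibble slice).
#' @param pauses pause table from [detect_pauses()] for this block.
#' @param rate_hz working rate.
#' @param expected_count optional known repetition count.
#' @param config see [segment_config()].
#' @param envelope the envelope used for pause detection (required for
#'   `boundary = "minimum"`).
#' @return tibble of repetitions: `movement`, `side`, `block`,
#'   `repetition`, `start_s`, `end_s` (session time), `source`,
#'   `review_flag`.
#' @export
segment_repetitions <- function(block, pauses, rate_hz,
                                expected_count = NULL,
                                config = segment_config(),
                                envelope = NULL) {
  n <- as.integer(round((block$end_s - block$start_s) * rate_hz))
  # sub-threshold runs touching the block edges are lead-in/lead-out, not
  # inter-repetition pauses: they cut nothing
  if (nrow(pauses) > 0) {
    interior <- pauses$start > 2L & pauses$end < n - 1L
    pauses <- pauses[interior, ]
  }
  if (nrow(pauses) == 0) {
    cuts_s <- c(0, n / rate_hz)
  } else {
    mids <- if (identical(config$boundary, "minimum") && !is.null(envelope)) {
      vapply(seq_len(nrow(pauses)), function(i) {
        idx <- pauses$start[i]:(pauses$end[i] - 1L)
        (idx[which.min(envelope[idx])] - 1L) / rate_hz
      }, numeric(1))
    } else {
      (pauses$start_s + pauses$end_s) / 2
    }
    cuts_s <- c(0, sort(mids), n / rate_hz)
  }
  reps <- tibble::tibble(
    start_s = cuts_s[-length(cuts_s)],
    end_s = cuts_s[-1]
  )
  reps <- reps[reps$end_s - reps$start_s >= config$min_rep_s, ]
  review <- nrow(reps) == 0 ||
    (!is.null(expected_count) && nrow(reps) != expected_count)
  if (nrow(reps) == 0) {
    return(tibble::tibble(
      movement = character(), side = character(), block = integer(),
      repetition = integer(), start_s = numeric(), end_s = numeric(),
      source = character(), review_flag = logical()
    ))
  }
  abs_start <- block$start_s + reps$start_s
  abs_end <- block$start_s + reps$end_s
  tibble::tibble(
    movement = block$movement, side = block$side, block = block$block,
    repetition = seq_len(nrow(reps)),
    start_s = abs_start,
    end_s = abs_end,
    source = "marker+auto",
    review_flag = review
  )
}

#' Segment a whole session into repetitions
#'
#' Convenience wrapper: splits on markers, computes the envelope per block,
#' detects pauses, and cuts repetitions. Optionally applies a boundary
#' override table (manual adjustments), replacing the automatic boundaries
#' for matching `(block, repetition)` rows.
#'
#' @param fsession a `filtered_session`.
#' @param config see [segment_config()].
#' @param expected_counts optional named vector movement -> expected
#'   repetition count.
#' @param overrides optional tibble `block, repetition, start_s, end_s`
#'   of manual boundary corrections.
#' @return tibble of repetitions across all blocks (columns as in
#'   [segment_repetitions()], plus `subject_id`).
#' @export
segment_session <- function(fsession, config = segment_config(),
                            expected_counts = NULL, overrides = NULL) {
  blocks <- split_movements(fsession)
  out <- lapply(seq_len(nrow(blocks)), function(i) {
    blk <- blocks[i, ]
    env <- velocity_envelope(blk$channels[[1]], config$envelope_placements)
    pauses <- detect_pauses(env, fsession$rate_hz, config$threshold_dps,
                            config$min_pause_s)
    expect_n <- if (!is.null(expected_counts)) {
      expected_counts[[blk$movement]] %||% NULL
    }
    segment_repetitions(blk, pauses, fsession$rate_hz, expect_n, config, env)
  })
  reps <- dplyr::bind_rows(out)
  if (nrow(reps) > 0) {
    reps <- dplyr::mutate(reps, subject_id = fsession$subject_id, .before = 1)
    if (!is.null(overrides) && nrow(overrides) > 0) {
      for (i in seq_len(nrow(overrides))) {
        hit <- reps$block == overrides$block[i] &
          reps$repetition == overrides$repetition[i]
        reps$start_s[hit] <- overrides$start_s[i]
        reps$end_s[hit] <- overrides$end_s[i]
        reps$source[hit] <- "manual-override"
        reps$review_flag[hit] <- FALSE
      }
    }
  }
  reps
}
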
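#' Spectral summary features
#'
#' Spectra are estimated by a single-segment Welch periodogram: the series
#' is mean-detrended, Hann-windowed, and zero-padded to a configurable
#' frequency grid (default 0.05 Hz). `dominant_frequency()` is the location
#' of the power maximum over (0, rate/2]; `mean_frequency()` is the
#' power-weighted spectral centroid over the same band. An all-zero (or
#' constant) series yields the 0 Hz sentinel with a flag.
#'
#' @param x numeric series (>= 32 samples).
#' @param rate_hz sampling rate.
#' @param grid_hz frequency-grid resolution for zero padding.
#' @return a list with `value` (Hz) and `flag` (TRUE when the sentinel was
#'   used).
#' @examples
#' t <- seq(0, 8, by = 1 / 32)
#' dominant_frequency(sin(2 * pi * 1.5 * t), 32)$value
#' @export
dominant_frequency <- function(x, rate_hz, grid_hz = 0.05) {
  ps <- periodogram(x, rate_hz, grid_hz)
  if (ps$flag) return(list(value = 0, flag = TRUE))
  list(value = ps$freq[which.max(ps$power)], flag = FALSE)
}

#' @rdname dominant_frequency
#' @export
mean_frequency <- function(x, rate_hz, grid_hz = 0.05) {
  ps <- periodogram(x, rate_hz, grid_hz)
  if (ps$flag) return(list(value = 0, flag = TRUE))
  list(value = sum(ps$freq * ps$power) / sum(ps$power), flag = FALSE)
}

# single-segment, Hann-windowed, zero-padded periodogram over (0, rate/2]
periodogram <- function(x, rate_hz, grid_hz = 0.05) {
  if (length(x) < 32) {
    stop_moveprof("series too short for spectral features (< 32 samples)",
                  "moveprof_extraction_error")
  }
  x <- x - mean(x)
  if (all(abs(x) < 1e-12)) {
    return(list(freq = numeric(0), power = numeric(0), flag = TRUE))
  }
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, length(x) - 1) / (length(x) - 1))
  xw <- x * w
  nfft <- max(length(x), as.integer(ceiling(rate_hz / grid_hz)))
  X <- fft(c(xw, numeric(nfft - length(xw))))
  half <- floor(nfft / 2)
  freq <- (1:half) * rate_hz / nfft
  power <- Mod(X[2:(half + 1)])^2
  list(freq = freq, power = power, flag = FALSE)
}

#' Orientation metrics from low-pass accelerometer
#'
#' Under the gravity-dominant assumption the low-pass accelerometer gives
#' the sensor's attitude: `pitch = atan2(-ax, sqrt(ay^2 + az^2))`,
#' `roll = atan2(ay, az)`, both in degrees per sample, summarized over the
#' repetition as mean and range. If the gravity magnitude stays below
#' 0.5 g for most of the window the attitude is unreliable: metrics are
#' still computed from the unit-normalized vector and flagged.
#'
#' @param ax,ay,az low-pass accelerometer axes (g).
#' @return list with `pitch_mean`, `roll_mean`, `pitch_range`,
#'   `roll_range` (degrees) and `flag`.
#' @examples
#' orientation_metrics(rep(-sin(pi / 6), 10), rep(0, 10),
#'                     rep(cos(pi / 6), 10))$pitch_mean # 30 degrees
#' @export
orientation_metrics <- function(ax, ay, az) {
  mag <- sqrt(ax^2 + ay^2 + az^2)
  flag <- mean(mag < 0.5) > 0.5
  pitch <- atan2(-ax, sqrt(ay^2 + az^2)) * 180 / pi
  roll <- atan2(ay, az) * 180 / pi
  list(
    pitch_mean = mean(pitch), roll_mean = mean(roll),
    pitch_range = diff(range(pitch)), roll_range = diff(range(roll)),
    flag = flag
  )
}

#' Normalized cross-correlation peak and lag
#'
#' Measures inter-limb synchrony: the normalized cross-correlation of two
#' equal-length series over lags `|l| <= max_lag_s`, returning the peak
#' coefficient (in `[-1, 1]` by absolute peak) and its signed lag in
#' seconds. Ties on the peak go to the smallest `|lag|`, then to the
#' negative lag. Zero-variance input yields the `(0, 0)` sentinel with a
#' flag.
#'
#' @param a,b equal-length numeric series.
#' @param rate_hz sampling rate.
#' @param max_lag_s maximum lag searched (s).
#' @return list with `peak`, `lag_s`, `flag`.
#' @examples
#' t <- seq(0, 10, by = 1 / 32)
#' a <- sin(2 * pi * 0.5 * t)
#' xcorr_features(a, -a, 32)$peak # -1
#' @export
xcorr_features <- function(a, b, rate_hz, max_lag_s = 2) {
  if (length(a) != length(b)) {
    stop_moveprof("cross-correlation inputs must have equal length",
                  "moveprof_extraction_error")
  }
  a <- a - mean(a)
  b <- b - mean(b)
  denom <- sqrt(sum(a^2) * sum(b^2))
  if (denom < 1e-12) {
    return(list(peak = 0, lag_s = 0, flag = TRUE))
  }
  max_lag <- min(length(a) - 1L, as.integer(round(max_lag_s * rate_hz)))
  lags <- -max_lag:max_lag
  r <- vapply(lags, function(l) {
    if (l >= 0) {
      sum(a[1:(length(a) - l)] * b[(1 + l):length(b)])
    } else {
      sum(a[(1 - l):length(a)] * b[1:(length(b) + l)])
    }
  }, numeric(1)) / denom
  # peak by |r|; ties -> smallest |lag|, then negative lag
  best <- order(-abs(r), abs(lags), lags)[1]
  list(peak = r[best], lag_s = lags[best] / rate_hz, flag = FALSE)
}

#' Extract the full feature vector for one repetition
#'
#' Computes every registry entry from the filtered session, in registry
#' order. Sentinel uses (zero spectra, zero-variance cross-correlation,
#' weak gravity) are counted in the `n_flags` attribute-free `flags` field.
#'
#' @param rep_row one repetition (a row of [segment_session()] output or
#'   the generator truth table): needs `start_s`, `end_s`.
#' @param fsession a `filtered_session` containing the repetition.
#' @param registry see [feature_registry()].
#' @return list with `values` (named numeric, length `nrow(registry)`) and
#'   `flags` (number of sentinel substitutions).
#' @export
extract_features <- function(rep_row, fsession, registry = feature_registry()) {
  rate <- fsession$rate_hz
  need <- unique(c(registry$placement,
                   registry$placement_b[!is.na(registry$placement_b)]))
  missing_pl <- setdiff(need, names(fsession$channels))
  if (length(missing_pl) > 0) {
    stop_moveprof(paste0("registry placement(s) absent from session: ",
                         paste(missing_pl, collapse = ", ")),
                  "moveprof_extraction_error")
  }
  i0 <- as.integer(floor(rep_row$start_s * rate)) + 1L
  i1 <- as.integer(ceiling(rep_row$end_s * rate))
  n_ch <- nrow(fsession$channels[[1]])
  i1 <- min(i1, n_ch)
  if (i1 - i0 + 1L < 32L) {
    stop_moveprof("repetition shorter than the minimum feature window",
                  "moveprof_extraction_error")
  }
  idx <- i0:i1
  values <- numeric(nrow(registry))
  names(values) <- registry$name
  flags <- 0L
  slices <- lapply(fsession$channels,
                   function(ch) lapply(ch, function(col) col[idx]))
  fam <- registry$family
  placement <- registry$placement
  placement_b <- registry$placement_b
  statistic <- registry$statistic
  # spectral: one periodogram per (placement, modality, axis, band) series,
  # shared between the dominant- and mean-frequency entries
  is_spec <- fam == "spectral"
  if (any(is_spec)) {
    col_of <- paste0(
      ifelse(registry$modality[is_spec] == "acc", "a", "g"),
      registry$axis[is_spec],
      ifelse(registry$modality[is_spec] == "acc", "_g", "_dps"),
      "_", registry$band[is_spec]
    )
    series_key <- paste(placement[is_spec], col_of)
    stat_spec <- statistic[is_spec]
    spec_idx <- which(is_spec)
    for (key in unique(series_key)) {
      sel <- series_key == key
      parts <- strsplit(key, " ")[[1]]
      ps <- periodogram(slices[[parts[1]]][[parts[2]]], rate)
      if (ps$flag) {
        values[spec_idx[sel]] <- 0
        flags <- flags + sum(sel)
      } else {
        tot <- sum(ps$power)
        for (k in which(sel)) {
          values[spec_idx[k]] <- if (stat_spec[k] == "domf") {
            ps$freq[which.max(ps$power)]
          } else {
            sum(ps$freq * ps$power) / tot
          }
        }
      }
    }
  }
  is_ori <- fam == "orientation"
  for (pl in unique(placement[is_ori])) {
    ch <- slices[[pl]]
    om <- orientation_metrics(ch$ax_g_lp, ch$ay_g_lp, ch$az_g_lp)
    sel <- which(is_ori & placement == pl)
    values[sel] <- unlist(om[statistic[sel]])
    flags <- flags + om$flag
  }
  is_xc <- fam == "xcorr"
  if (any(is_xc)) {
    pair_key <- paste(placement[is_xc], placement_b[is_xc])
    xc_idx <- which(is_xc)
    for (key in unique(pair_key)) {
      parts <- strsplit(key, " ")[[1]]
      xr <- xcorr_features(slices[[parts[1]]]$gmag_bp,
                           slices[[parts[2]]]$gmag_bp, rate)
      sel <- pair_key == key
      for (k in which(sel)) {
        values[xc_idx[k]] <- if (statistic[xc_idx[k]] == "peak") {
          xr$peak
        } else {
          xr$lag_s
        }
      }
      flags <- flags + xr$flag
    }
  }
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values))
    values[bad] <- 0
    flags <- flags + length(bad)
  }
  list(values = values, flags = flags)
}

#' Build a cohort feature table
#'
#' Runs preprocessing, segmentation (or the ground-truth boundaries), and
#' feature extraction over a set of sessions, returning the repetitions x
#' features tibble that feeds selection and modeling. The registry hash is
#' attached as an attribute.
#'
#' @param sessions list of `imu_session` objects (e.g.
#'   `generate_cohort()$sessions`).
#' @param registry see [feature_registry()].
#' @param use_truth_boundaries if `TRUE` (default) and sessions carry
#'   ground-truth annotations, repetition boundaries and grades come from
#'   the truth table; otherwise boundaries come from [segment_session()]
#'   and grades from the session scores.
#' @param preprocess_cfg,segment_cfg stage configurations.
#' @param progress unused; kept for CLI symmetry.
#' @return feature table tibble: `repetition_id`, `subject_id`,
#'   `movement`, `side`, `grade`, then the registry features in canonical
#'   order.
#' @export
extract_cohort_features <- function(sessions,
                                    registry = feature_registry(),
                                    use_truth_boundaries = TRUE,
                                    preprocess_cfg = preprocess_config(),
                                    segment_cfg = segment_config(),
                                    progress = FALSE) {
  rows <- lapply(sessions, function(sess) {
    fs <- preprocess_session(sess, preprocess_cfg)
    reps <- if (use_truth_boundaries && !is.null(sess$truth)) {
      dplyr::mutate(sess$truth, subject_id = sess$subject_id)
    } else {
      seg <- segment_session(fs, segment_cfg)
      add_grades_from_scores(seg, sess$scores)
    }
    extract_rep_features(reps, fs, registry)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "registry_hash") <- registry_hash(registry)
  out
}

extract_rep_features <- function(reps, fsession, registry) {
  if (nrow(reps) == 0) return(tibble::tibble())
  feats <- lapply(seq_len(nrow(reps)), function(i) {
    extract_features(reps[i, ], fsession, registry)$values
  })
  mat <- do.call(rbind, feats)
  lab <- tibble::tibble(
    repetition_id = sprintf("%s_b%02d_r%02d", fsession$subject_id,
                            reps$block, reps$repetition),
    subject_id = fsession$subject_id,
    movement = reps$movement,
    side = reps$side,
    grade = if ("grade" %in% names(reps)) reps$grade else NA_character_
  )
  dplyr::bind_cols(lab, tibble::as_tibble(mat))
}

add_grades_from_scores <- function(reps, scores) {
  if (nrow(reps) == 0) return(reps)
  scores <- dplyr::mutate(scores, grade = discretize_score(.data$value))
  dplyr::left_join(reps, scores[, c("movement", "side", "grade")],
                   by = c("movement", "side"))
}
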
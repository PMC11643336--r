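#' Generate one subject's synthetic session
#'
#' Builds a full 13-sensor, 100 Hz session for one subject: one marked block
#' per (movement, side), each holding the configured number of repetitions
#' separated by low-velocity pauses. Within a repetition, each site follows
#' the archetype's harmonic waveform under a smooth on/off envelope; the
#' accelerometer reads gravity through the time-varying pitch/roll posture,
#' the gyroscope carries the movement oscillation, and the magnetometer
#' reads a constant earth field through the same rotation. Grade-dependent
#' degradation (jerk noise, tempo/amplitude jitter, coordination error) and
#' subject-level random effects (tempo, amplitude, posture, phase offsets)
#' are superimposed. Ground-truth repetition boundaries and grades are
#' attached as annotations.
#'
#' @param archetypes named list from [movement_archetypes()].
#' @param grades a single grade (`"low"`, `"medium"`, `"high"`) applied to
#'   every movement, or a named character vector keyed by movement.
#' @param config a [cohort_config()] (its `movements`,
#'   `repetitions_per_movement`, `bilateral`, `pause_duration_s`, and
#'   `rate_hz` fields are used).
#' @param seed integer; fully determines the session.
#' @param subject_id subject label.
#' @param profiles degradation profiles, see [proficiency_profiles()].
#' @return an `imu_session` with `truth` annotations (one row per
#'   repetition: movement, side, block, repetition, start_s, end_s, grade,
#'   score).
#' @examples
#' cfg <- cohort_config(movements = "RTP", seed = 7)
#' s <- generate_subject(movement_archetypes(), "high", cfg, seed = 7)
#' nrow(s$truth)
#' @export
generate_subject <- function(archetypes, grades, config, seed,
                             subject_id = "S01",
                             profiles = proficiency_profiles()) {
  stopifnot(length(archetypes) > 0)
  movements <- intersect(config$movements, names(archetypes))
  if (length(movements) == 0) {
    stop_moveprof("no requested movement has an archetype",
                  "moveprof_config_error")
  }
  if (length(grades) == 1 && is.null(names(grades))) {
    grades <- setNames(rep(grades, length(movements)), movements)
  }
  if (!all(movements %in% names(grades))) {
    stop_moveprof("grades must cover every requested movement",
                  "moveprof_config_error")
  }
  if (!all(grades %in% proficiency_grades())) {
    stop_moveprof("grades must be low/medium/high", "moveprof_config_error")
  }
  for (m in movements) check_archetype_ranges(archetypes[[m]], profiles)

  with_seed(seed, {
    subj <- draw_subject_effects()
    rate <- config$rate_hz
    gap_s <- 3 # quiet standing between blocks
    blocks <- list()
    truth <- list()
    markers <- list()
    scores <- list()
    t_cursor <- gap_s
    block_idx <- 0L
    for (m in movements) {
      sides <- if (config$bilateral && m %in% bilateral_movements()) {
        c("right", "left")
      } else "na"
      prof <- profiles[profiles$grade == grades[[m]], ]
      score_val <- sample_score_for_grade(grades[[m]])
      for (side in sides) {
        block_idx <- block_idx + 1L
        blk <- synth_block(archetypes[[m]], prof, subj, config, side,
                           profiles)
        blocks[[block_idx]] <- blk
        markers[[block_idx]] <- tibble::tibble(
          movement = m, side = side,
          start_s = t_cursor, end_s = t_cursor + blk$duration_s
        )
        truth[[block_idx]] <- dplyr::mutate(
          blk$truth,
          movement = m, side = side, block = block_idx,
          start_s = .data$start_s + t_cursor,
          end_s = .data$end_s + t_cursor,
          grade = grades[[m]], score = score_val
        )
        scores[[paste(m, side)]] <- tibble::tibble(
          movement = m, side = side, value = score_val
        )
        t_cursor <- t_cursor + blk$duration_s + gap_s
      }
    }
    total_n <- as.integer(round(t_cursor * rate)) + 1L
    channels <- assemble_channels(blocks, markers, total_n, rate)
    truth <- dplyr::bind_rows(truth)
    truth <- truth[, c("movement", "side", "block", "repetition",
                       "start_s", "end_s", "grade", "score")]
    imu_session(subject_id, channels,
                dplyr::bind_rows(markers),
                dplyr::bind_rows(scores), truth)
  })
}

# amplitude headroom check against hardware ranges
check_archetype_ranges <- function(arch, profiles) {
  harm_sum <- sum(abs(arch$harmonics$relamp)) / sum(arch$harmonics$relamp[1])
  amp_head <- 1 + 3 * max(profiles$amplitude_cv)
  max_gyro <- max(arch$sites$gyro_amp) * amp_head * 1.3
  if (max_gyro > sensor_ranges()[["gyro_dps"]]) {
    stop_moveprof(
      sprintf("archetype %s: gyroscope amplitude %g deg/s exceeds sensor range",
              arch$name, max_gyro),
      "moveprof_range_error"
    )
  }
  max_tilt <- max(arch$sites$tilt_amp) * amp_head
  if (max_tilt > 90) {
    stop_moveprof(
      sprintf("archetype %s: tilt amplitude %g deg exceeds the gravity model",
              arch$name),
      "moveprof_range_error"
    )
  }
  invisible(arch)
}

draw_subject_effects <- function() {
  pl <- body_placements()
  list(
    tempo_mult = exp(stats::rnorm(1, 0, 0.06)),
    amp_mult = exp(stats::rnorm(1, 0, 0.04)),
    pitch_off = stats::rnorm(13, 0, 2.5),
    roll_off = stats::rnorm(13, 0, 2.5),
    phase_off = stats::rnorm(13, 0, 0.15)
  )
}

sample_score_for_grade <- function(grade) {
  switch(grade,
    low = sample(c(1.5, 2, 2.5), 1),
    medium = sample(c(3, 3.5), 1),
    high = sample(c(4, 4.5, 5), 1)
  )
}

# sensor noise scales (white) and jerk-noise unit scales
noise_scales <- function() {
  list(accel_white_g = 0.012, gyro_white_dps = 0.8, mag_white_G = 0.004,
       accel_jerk_g = 0.06, gyro_jerk_dps = 25)
}

# band-limited (2-6 Hz) unit-variance noise via FFT masking
bandlimited_noise <- function(n, rate, lo = 2, hi = 6) {
  x <- stats::rnorm(n)
  X <- fft(x)
  f <- (seq_len(n) - 1) * rate / n
  f <- pmin(f, rate - f) # two-sided
  X[f < lo | f > hi] <- 0
  y <- Re(fft(X, inverse = TRUE)) / n
  s <- sd(y)
  if (s < 1e-12) return(numeric(n))
  y / s
}

# Tukey-style on/off envelope over a repetition, ramp fraction `frac`
rep_envelope <- function(tau, frac = 0.15) {
  w <- rep(1, length(tau))
  lo <- tau < frac
  hi <- tau > 1 - frac
  w[lo] <- 0.5 * (1 - cos(pi * tau[lo] / frac))
  w[hi] <- 0.5 * (1 - cos(pi * (1 - tau[hi]) / frac))
  w
}

# world-to-sensor rotation of a field vector given pitch/roll in degrees
rotate_to_sensor <- function(field, pitch_deg, roll_deg) {
  p <- pitch_deg * pi / 180
  r <- roll_deg * pi / 180
  ux <- field[1] * cos(p) - field[3] * sin(p)
  uy <- rep(field[2], length(p))
  uz <- field[1] * sin(p) + field[3] * cos(p)
  list(
    x = ux,
    y = uy * cos(r) + uz * sin(r),
    z = -uy * sin(r) + uz * cos(r)
  )
}

# synthesize one movement block for all 13 sensors
synth_block <- function(arch, prof, subj, config, side, profiles) {
  rate <- config$rate_hz
  n_reps <- unname(config$repetitions_per_movement[[arch$name]] %||%
                     config$repetitions_per_movement[[1]])
  lead_s <- 0.6
  period <- (1 / arch$fundamental_hz) * subj$tempo_mult

  trunc_norm <- function(n, sd_) {
    z <- stats::rnorm(n, 0, 1)
    pmin(pmax(z, -2.5), 2.5) * sd_
  }
  ge <- arch$grade_expression
  rep_periods <- period * (1 + ge[["tempo_dir"]] * prof$tempo_bias) *
    (1 + trunc_norm(n_reps, prof$tempo_jitter_cv * ge[["tempo"]]))
  rep_amps <- subj$amp_mult * (1 + ge[["amp_dir"]] * prof$amp_bias) *
    (1 + trunc_norm(n_reps, prof$amplitude_cv * ge[["amp"]]))
  pauses <- pmax(0.3 * config$pause_duration_s,
                 config$pause_duration_s + trunc_norm(n_reps - 1, 0.05))
  # per-rep, per-limb-group coordination error (radians)
  coord_err <- matrix(stats::rnorm(n_reps * 4, 0,
                                   prof$coordination_error_sd * ge[["coord"]]),
                      nrow = n_reps,
                      dimnames = list(NULL, c("arm_l", "arm_r", "leg_l",
                                              "leg_r")))
  # rep-to-rep postural sway: the whole-body stance is re-taken for every
  # repetition, so per-repetition orientation summaries vary within a block
  sway_pitch <- stats::rnorm(n_reps, 0, 2)
  sway_roll <- stats::rnorm(n_reps, 0, 2)

  # mirror the template for the left-foot-forward variant
  sites <- arch$sites
  if (side == "left") sites <- mirror_sites(sites)

  starts <- lead_s + c(0, cumsum(rep_periods[-n_reps] +
                                   if (n_reps > 1) pauses else numeric(0)))
  ends <- starts + rep_periods
  duration <- ends[n_reps] + lead_s
  n <- as.integer(round(duration * rate))
  duration <- n / rate # align block length to the sample grid
  t <- (seq_len(n) - 1) / rate

  # per-sample repetition index and within-rep phase tau
  rep_of <- rep(0L, n)
  tau <- numeric(n)
  for (i in seq_len(n_reps)) {
    in_rep <- t >= starts[i] & t < ends[i]
    rep_of[in_rep] <- i
    tau[in_rep] <- (t[in_rep] - starts[i]) / rep_periods[i]
  }
  active <- rep_of > 0L
  w <- numeric(n)
  for (i in seq_len(n_reps)) {
    # ramp length capped at 0.4 s so motion onset/offset stays sharp even
    # for slow movements
    frac_i <- min(0.15, 0.4 / rep_periods[i])
    sel <- rep_of == i
    w[sel] <- rep_envelope(tau[sel], frac_i)
  }
  amp_t <- numeric(n)
  amp_t[active] <- rep_amps[rep_of[active]]

  # jerk-noise level for this grade: jerk_dir = +1 reads the profile as-is
  # (novices are shaky); jerk_dir = -1 mirrors it about the medium level
  # (novices are stiff and dynamically flat, experts show richer high-band
  # content); fractional directions interpolate
  jerk_mid <- profiles$jerk_noise_sd[profiles$grade == "medium"]
  jerk_sd_eff <- max(0, jerk_mid +
                       ge[["jerk_dir"]] * (prof$jerk_noise_sd - jerk_mid))
  harm <- arch$harmonics
  hnorm <- sum(harm$relamp)
  pl <- body_placements()
  ns <- noise_scales()
  sensors <- vector("list", 13)
  names(sensors) <- sites$site
  group_key <- ifelse(pl$segment %in% c("upper_arm", "wrist"),
                      paste0("arm_", substr(pl$side, 1, 1)),
                      ifelse(pl$segment %in% c("thigh", "shank", "ankle"),
                             paste0("leg_", substr(pl$side, 1, 1)), "trunk"))
  for (k in seq_len(13)) {
    st <- sites[k, ]
    ph_subj <- subj$phase_off[k]
    # grade-dependent inter-limb timing drift: the legs systematically
    # lead or lag, in a movement-specific direction
    if (startsWith(group_key[k], "leg")) {
      ph_subj <- ph_subj + ge[["coord_dir"]] * prof$coord_bias
    }
    ph_err_t <- numeric(n)
    if (group_key[k] != "trunk") {
      ph_err_t[active] <- coord_err[rep_of[active], group_key[k]]
    }
    osc <- function(extra_phase) {
      s <- numeric(n)
      for (j in seq_len(nrow(harm))) {
        s <- s + harm$relamp[j] *
          sin(2 * pi * harm$h[j] * tau + harm$h[j] *
                (st$phase + ph_subj + ph_err_t) + extra_phase)
      }
      s * w / hnorm
    }
    sway_p_t <- numeric(n)
    sway_r_t <- numeric(n)
    sway_p_t[active] <- sway_pitch[rep_of[active]]
    sway_r_t[active] <- sway_roll[rep_of[active]]
    pitch <- st$pitch_mean + subj$pitch_off[k] + sway_p_t +
      st$tilt_amp * amp_t * osc(0)
    roll <- st$roll_mean + subj$roll_off[k] + sway_r_t +
      0.6 * st$tilt_amp * amp_t * osc(pi / 2)
    grav <- rotate_to_sensor(c(0, 0, 1), pitch, roll)
    mag <- rotate_to_sensor(c(0.2, 0, -0.45), pitch, roll)
    g_amp <- st$gyro_amp * amp_t
    jerk <- function(unit) {
      unit * jerk_sd_eff * ge[["jerk"]] * w * bandlimited_noise(n, rate)
    }
    sensors[[k]] <- tibble::tibble(
      t_s = t,
      ax_g = -sin(pitch * pi / 180) + jerk(ns$accel_jerk_g) +
        stats::rnorm(n, 0, ns$accel_white_g),
      ay_g = grav$y + jerk(ns$accel_jerk_g) +
        stats::rnorm(n, 0, ns$accel_white_g),
      az_g = grav$z + jerk(ns$accel_jerk_g) +
        stats::rnorm(n, 0, ns$accel_white_g),
      gx_dps = 0.6 * g_amp * osc(pi / 2) + jerk(ns$gyro_jerk_dps) +
        stats::rnorm(n, 0, ns$gyro_white_dps),
      gy_dps = 1.0 * g_amp * osc(0) + jerk(ns$gyro_jerk_dps) +
        stats::rnorm(n, 0, ns$gyro_white_dps),
      gz_dps = 0.8 * g_amp * osc(pi / 4) + jerk(ns$gyro_jerk_dps) +
        stats::rnorm(n, 0, ns$gyro_white_dps),
      mx_G = mag$x + stats::rnorm(n, 0, ns$mag_white_G),
      my_G = mag$y + stats::rnorm(n, 0, ns$mag_white_G),
      mz_G = mag$z + stats::rnorm(n, 0, ns$mag_white_G)
    )
  }

  # ground-truth repetition intervals use the cut-point convention: each
  # repetition runs from the midpoint of the preceding pause (or block
  # start) to the midpoint of the following pause (or block end)
  cuts <- c(0, (ends[-n_reps] + starts[-1]) / 2, duration)
  truth <- tibble::tibble(
    repetition = seq_len(n_reps),
    start_s = cuts[-length(cuts)],
    end_s = cuts[-1]
  )
  list(sensors = sensors, truth = truth, duration_s = duration, n = n)
}

# swap left/right site parameters (left-foot-forward variant)
mirror_sites <- function(sites) {
  pl <- body_placements()
  mirrored <- sites
  for (i in seq_len(nrow(pl))) {
    if (pl$side[i] == "center") next
    twin <- paste0(pl$segment[i], if (pl$side[i] == "left") "_r" else "_l")
    j <- match(twin, pl$site)
    mirrored[i, c("gyro_amp", "tilt_amp", "pitch_mean", "phase")] <-
      sites[j, c("gyro_amp", "tilt_amp", "pitch_mean", "phase")]
    mirrored$roll_mean[i] <- -sites$roll_mean[j]
  }
  mirrored
}

# stitch block signals into continuous whole-session channels
assemble_channels <- function(blocks, markers, total_n, rate) {
  ns <- noise_scales()
  pl <- body_placements()
  channels <- vector("list", 13)
  names(channels) <- pl$site
  for (k in seq_len(13)) {
    t <- (seq_len(total_n) - 1) / rate
    base <- tibble::tibble(
      t_s = t,
      ax_g = stats::rnorm(total_n, 0, ns$accel_white_g),
      ay_g = stats::rnorm(total_n, 0, ns$accel_white_g),
      az_g = 1 + stats::rnorm(total_n, 0, ns$accel_white_g),
      gx_dps = stats::rnorm(total_n, 0, ns$gyro_white_dps),
      gy_dps = stats::rnorm(total_n, 0, ns$gyro_white_dps),
      gz_dps = stats::rnorm(total_n, 0, ns$gyro_white_dps),
      mx_G = 0.2 + stats::rnorm(total_n, 0, ns$mag_white_G),
      my_G = stats::rnorm(total_n, 0, ns$mag_white_G),
      mz_G = -0.45 + stats::rnorm(total_n, 0, ns$mag_white_G)
    )
    for (b in seq_along(blocks)) {
      i0 <- as.integer(round(markers[[b]]$start_s * rate)) + 1L
      seg <- blocks[[b]]$sensors[[k]]
      idx <- i0:(i0 + nrow(seg) - 1L)
      for (cc in setdiff(sensor_csv_columns(), "t_s")) {
        base[[cc]][idx] <- seg[[cc]]
      }
    }
    # clamp to hardware ranges (noise tails only; the template itself is
    # validated against the ranges up front)
    rng <- sensor_ranges()
    for (cc in c("ax_g", "ay_g", "az_g")) {
      base[[cc]] <- pmin(pmax(base[[cc]], -rng[["accel_g"]]), rng[["accel_g"]])
    }
    for (cc in c("gx_dps", "gy_dps", "gz_dps")) {
      base[[cc]] <- pmin(pmax(base[[cc]], -rng[["gyro_dps"]]), rng[["gyro_dps"]])
    }
    for (cc in c("mx_G", "my_G", "mz_G")) {
      base[[cc]] <- pmin(pmax(base[[cc]], -rng[["mag_G"]]), rng[["mag_G"]])
    }
    attr(base, "rate_hz") <- rate
    channels[[k]] <- base
  }
  channels
}

#' Generate a synthetic cohort with ground truth
#'
#' One session per subject, with subject-movement grades assigned by
#' largest-remainder rounding of `class_proportions` over a seeded
#' permutation of subjects (so each movement sees every grade with positive
#' proportion, as a real cohort with mixed skill would). Per-subject random
#' effects make subjects systematically different, which is what makes
#' leave-one-subject-out validation meaningful.
#'
#' @param config a [cohort_config()].
#' @return list with `sessions` (named list of `imu_session`), `truth`
#'   (tibble pooling all per-repetition ground truth with `subject_id`),
#'   and `grades` (tibble subject x movement grade assignment).
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_config(n_subjects = 2, movements = "RTP"))
#' nrow(cohort$truth)
#' }
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  archetypes <- movement_archetypes(overlap = config$overlap)
  subject_ids <- sprintf("S%02d", seq_len(config$n_subjects))
  seeds <- derive_seeds(config$seed, config$n_subjects + 1L)
  grades_tbl <- with_seed(seeds[config$n_subjects + 1L], {
    assign_grades(subject_ids, config$movements, config$class_proportions)
  })
  sessions <- vector("list", config$n_subjects)
  names(sessions) <- subject_ids
  truth <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    g <- grades_tbl[grades_tbl$subject_id == subject_ids[i], ]
    grades <- setNames(g$grade, g$movement)
    sessions[[i]] <- generate_subject(archetypes, grades, config,
                                      seed = seeds[i],
                                      subject_id = subject_ids[i])
    truth[[i]] <- dplyr::mutate(sessions[[i]]$truth,
                                subject_id = subject_ids[i],
                                .before = 1)
  }
  list(sessions = sessions, truth = dplyr::bind_rows(truth),
       grades = grades_tbl)
}

# largest-remainder grade counts, assigned over a permutation of subjects
assign_grades <- function(subject_ids, movements, proportions) {
  n <- length(subject_ids)
  target <- proportions * n
  counts <- floor(target)
  rem <- target - counts
  short <- n - sum(counts)
  if (short > 0) {
    top_up <- order(rem, decreasing = TRUE)[seq_len(short)]
    counts[top_up] <- counts[top_up] + 1
  }
  out <- lapply(movements, function(m) {
    pool <- rep(proficiency_grades(), times = counts)
    tibble::tibble(
      subject_id = subject_ids,
      movement = m,
      grade = sample(pool, n)
    )
  })
  dplyr::bind_rows(out)
}
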
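#' Movement archetypes for the synthetic IMU generator
#'
#' The generator has no access to real recordings, so each of the six
#' protocol movements is modeled as a minimal kinematic archetype: a
#' repetition tempo (fundamental frequency), a stack of phase-locked
#' harmonics shaping the within-repetition waveform, a per-site posture
#' (mean pitch/roll of the gravity vector) with a movement-specific tilt
#' amplitude, per-site gyroscope amplitudes weighted by which limbs the
#' movement emphasizes, and a per-site phase offset encoding inter-limb
#' coordination. These are exactly the properties the downstream feature
#' families (spectral, orientation, cross-correlation) are designed to
#' read out.
#'
#' Two archetypes — the GST and WHLC analogs — are deliberately similar:
#' WHLC is defined by interpolating from the GST template toward a fully
#' distinct variant, with `overlap` controlling how much of the distinction
#' is removed (`overlap = 1` makes them identical, `0` fully distinct).
#' This reproduces the qualitative confusability of the two movements
#' that share common motion patterns.
#'
#' @param overlap fraction in `[0, 1)` of the GST/WHLC distinction removed
#'   (default 0.6).
#' @return named list of `movement_archetype` objects, one per label in
#'   [movement_labels()].
#' @examples
#' arch <- movement_archetypes()
#' arch$RTP$fundamental_hz
#' @export
movement_archetypes <- function(overlap = 0.6) {
  stopifnot(is_scalar_number(overlap), overlap >= 0, overlap < 1)
  a <- list(
    RTP = make_archetype(
      name = "RTP", fundamental_hz = 0.40,
      harmonics = c(`1` = 1, `2` = 0.25, `3` = 0.08),
      limb_weights = c(upper = 1.2, lower = 0.4, trunk = 0.6),
      trunk_pitch = 0, trunk_roll = 0, arm_pitch = -40, thigh_pitch = 5,
      phases = c(arm_l = 0, arm_r = 0, leg_l = 0.3 * pi, leg_r = 0.3 * pi),
      grade_expression = c(jerk = 1.5, tempo = 0.6, amp = 0.6, coord = 0.4, jerk_dir = 1,
                           tempo_dir = 1, amp_dir = -1, coord_dir = 1)
    ),
    PUSH = make_archetype(
      name = "PUSH", fundamental_hz = 0.31,
      harmonics = c(`1` = 1, `2` = 0.40, `3` = 0.12),
      limb_weights = c(upper = 1.1, lower = 0.7, trunk = 0.8),
      trunk_pitch = 8, trunk_roll = 0, arm_pitch = -20, thigh_pitch = 10,
      phases = c(arm_l = 0, arm_r = 0, leg_l = 0.5 * pi, leg_r = 0.5 * pi),
      grade_expression = c(jerk = 1.0, tempo = 1.0, amp = 1.2, coord = 1.2, jerk_dir = -1,
                           tempo_dir = -1, amp_dir = -1, coord_dir = 1)
    ),
    GST = make_archetype(
      name = "GST", fundamental_hz = 0.20,
      harmonics = c(`1` = 1, `2` = 0.35, `4` = 0.10),
      limb_weights = c(upper = 1.0, lower = 0.9, trunk = 1.0),
      trunk_pitch = 14, trunk_roll = 4, arm_pitch = -25, thigh_pitch = 15,
      phases = c(arm_l = 0, arm_r = 0.9 * pi, leg_l = 0.25 * pi,
                 leg_r = 1.15 * pi),
      grade_expression = c(jerk = 0.5, tempo = 0.6, amp = 0.7, coord = 1.4, jerk_dir = 1,
                           tempo_dir = 1, amp_dir = 1, coord_dir = -1)
    ),
    BKTS = make_archetype(
      name = "BKTS", fundamental_hz = 0.25,
      harmonics = c(`1` = 1, `2` = 0.50, `3` = 0.15),
      limb_weights = c(upper = 0.7, lower = 1.2, trunk = 0.9),
      trunk_pitch = 18, trunk_roll = 0, arm_pitch = -15, thigh_pitch = 20,
      phases = c(arm_l = 0, arm_r = pi, leg_l = pi, leg_r = 0),
      grade_expression = c(jerk = 0.8, tempo = 0.8, amp = 1.3, coord = 0.5, jerk_dir = -1,
                           tempo_dir = -1, amp_dir = -1, coord_dir = -1)
    ),
    GR = make_archetype(
      name = "GR", fundamental_hz = 0.155,
      harmonics = c(`1` = 1, `3` = 0.20),
      limb_weights = c(upper = 0.6, lower = 1.3, trunk = 0.7),
      trunk_pitch = 5, trunk_roll = 6, arm_pitch = -30, thigh_pitch = 45,
      phases = c(arm_l = 0, arm_r = 0, leg_l = 0.2 * pi, leg_r = 0.7 * pi),
      grade_expression = c(jerk = 1.3, tempo = 1.1, amp = 0.5, coord = 0.6, jerk_dir = 1,
                           tempo_dir = 1, amp_dir = -1, coord_dir = -1)
    )
  )
  # WHLC: interpolate from GST toward a fully distinct template
  whlc_distinct <- make_archetype(
    name = "WHLC", fundamental_hz = 0.30,
    harmonics = c(`1` = 1, `2` = 0.35, `4` = 0.10),
    limb_weights = c(upper = 1.15, lower = 0.75, trunk = 1.1),
    trunk_pitch = 2, trunk_roll = 18, arm_pitch = -45, thigh_pitch = 2,
    phases = c(arm_l = 0, arm_r = pi, leg_l = 0.85 * pi, leg_r = 1.85 * pi),
    grade_expression = c(jerk = 0.5, tempo = 0.5, amp = 0.9, coord = 1.4, jerk_dir = -1,
                         tempo_dir = -1, amp_dir = 1, coord_dir = -1)
  )
  a$WHLC <- interpolate_archetype(a$GST, whlc_distinct, 1 - overlap)
  a$WHLC$name <- "WHLC"
  a[movement_labels()]
}

# per-site base gyroscope amplitude (deg/s) and tilt amplitude (degrees)
site_base_params <- function() {
  tibble::tibble(
    site = body_placements()$site,
    group = c("trunk", "trunk", "trunk",
              "arm", "arm", "arm", "arm",
              "leg", "leg", "leg", "leg", "leg", "leg"),
    gyro_base = c(25, 22, 18, 70, 70, 90, 90, 40, 40, 50, 50, 55, 55),
    tilt_base = c(6, 5, 4, 25, 25, 30, 30, 15, 15, 12, 12, 10, 10)
  )
}

make_archetype <- function(name, fundamental_hz, harmonics, limb_weights,
                           trunk_pitch, trunk_roll, arm_pitch, thigh_pitch,
                           phases,
                           grade_expression = c(jerk = 1, tempo = 1,
                                                amp = 1, coord = 1,
                                                jerk_dir = 1,
                                                tempo_dir = 0,
                                                amp_dir = 0,
                                                coord_dir = 0)) {
  base <- site_base_params()
  pl <- body_placements()
  weight <- c(trunk = limb_weights[["trunk"]],
              arm = limb_weights[["upper"]],
              leg = limb_weights[["lower"]])[base$group]
  pitch_mean <- numeric(13)
  roll_mean <- numeric(13)
  phase <- numeric(13)
  for (i in seq_len(13)) {
    grp <- base$group[i]
    side <- pl$side[i]
    seg <- pl$segment[i]
    pitch_mean[i] <- switch(grp,
      trunk = trunk_pitch,
      arm = arm_pitch,
      leg = if (seg == "thigh") thigh_pitch else thigh_pitch / 3
    )
    roll_mean[i] <- switch(grp,
      trunk = trunk_roll,
      arm = if (side == "left") -8 else 8,
      leg = if (side == "left") -4 else 4
    )
    phase[i] <- if (grp == "trunk") 0 else {
      key <- paste0(if (grp == "arm") "arm" else "leg",
                    if (side == "left") "_l" else "_r")
      phases[[key]]
    }
  }
  structure(
    list(
      name = name,
      fundamental_hz = fundamental_hz,
      grade_expression = grade_expression,
      harmonics = tibble::tibble(
        h = as.numeric(names(harmonics)),
        relamp = as.numeric(harmonics)
      ),
      sites = tibble::tibble(
        site = base$site,
        group = base$group,
        gyro_amp = base$gyro_base * weight,
        tilt_amp = base$tilt_base * weight,
        pitch_mean = pitch_mean,
        roll_mean = roll_mean,
        phase = phase
      )
    ),
    class = "movement_archetype"
  )
}

# linear interpolation between two archetypes (alpha = 0 -> from)
interpolate_archetype <- function(from, to, alpha) {
  out <- from
  out$fundamental_hz <- (1 - alpha) * from$fundamental_hz +
    alpha * to$fundamental_hz
  # how a movement expresses proficiency is its own property: the kinematic
  # template is blended, the grade channels are not
  out$grade_expression <- to$grade_expression
  num <- c("gyro_amp", "tilt_amp", "pitch_mean", "roll_mean", "phase")
  for (cc in num) {
    out$sites[[cc]] <- (1 - alpha) * from$sites[[cc]] + alpha * to$sites[[cc]]
  }
  out
}

#' Proficiency-grade degradation profiles
#'
#' Execution quality is expressed in the generator as four degradation
#' parameters, all strictly decreasing from low to high grade: `jerk_noise_sd`
#' (scale of band-limited 2-6 Hz "jerkiness" noise added to accelerometer and
#' gyroscope within repetitions, in units of the nominal noise scale),
#' `tempo_jitter_cv` (coefficient of variation of per-repetition period),
#' `amplitude_cv` (CV of per-repetition amplitude), and
#' `coordination_error_sd` (per-repetition inter-limb phase noise, radians).
#' Three further magnitudes — `tempo_bias`, `amp_bias`, and `coord_bias`
#' (a systematic arm-leg phase lead/lag, radians) — set how far the mean
#' tempo, amplitude, and inter-limb timing drift from the archetype's
#' nominal values; the *direction* of each drift is movement-specific (a
#' novice rushes some movements and drags others, undershoots some
#' amplitudes and overshoots others, lets the legs lead in one movement
#' and lag in another), so the signs live in the archetype's
#' `grade_expression`. High-grade values are small but strictly positive:
#' even expert movement is not noiseless.
#'
#' @return tibble with one row per grade.
#' @examples
#' proficiency_profiles()
#' @export
proficiency_profiles <- function() {
  tibble::tibble(
    grade = proficiency_grades(),
    jerk_noise_sd = c(0.30, 0.17, 0.09),
    tempo_jitter_cv = c(0.09, 0.06, 0.03),
    amplitude_cv = c(0.18, 0.11, 0.05),
    coordination_error_sd = c(0.48, 0.33, 0.20),
    tempo_bias = c(0.05, 0.022, 0.006),
    amp_bias = c(0.12, 0.055, 0.015),
    coord_bias = c(0.50, 0.22, 0.06)
  )
}

#' Cohort configuration for the synthetic generator
#'
#' Describes a simulated study: number of subjects, movement subset,
#' repetitions per movement block, bilateral practice (every movement except
#' the RTP analog is performed once with each foot forward), pause length
#' between repetitions, per-movement grade proportions, and a master seed
#' that fully determines the output.
#'
#' @param n_subjects number of subjects (>= 2; leave-one-subject-out
#'   validation requires at least two).
#' @param movements subset of [movement_labels()].
#' @param repetitions_per_movement repetitions per block (single count or
#'   named per-movement vector; the protocol used 6 or 9).
#' @param bilateral if `TRUE`, movements other than RTP get a left and a
#'   right block.
#' @param pause_duration_s nominal pause between repetitions (s).
#' @param class_proportions length-3 numeric (low, medium, high) summing
#'   to 1; subject-movement grades are assigned by largest-remainder
#'   rounding so every grade with positive proportion is represented.
#' @param overlap GST/WHLC template overlap, see [movement_archetypes()].
#' @param rate_hz raw sampling rate (Hz).
#' @param seed master seed (integer).
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 8,
                          movements = movement_labels(),
                          repetitions_per_movement = 6,
                          bilateral = TRUE,
                          pause_duration_s = 0.5,
                          class_proportions = c(low = 1 / 3, medium = 1 / 3,
                                                high = 1 / 3),
                          overlap = 0.6,
                          rate_hz = 100,
                          seed = 1L) {
  if (!is_scalar_number(n_subjects) || n_subjects < 2) {
    stop_moveprof("n_subjects must be at least 2", "moveprof_config_error")
  }
  movements <- match.arg(movements, movement_labels(), several.ok = TRUE)
  if (abs(sum(class_proportions) - 1) > 1e-8 || any(class_proportions < 0)) {
    stop_moveprof("class_proportions must be non-negative and sum to 1",
                  "moveprof_config_error")
  }
  if (length(class_proportions) != 3) {
    stop_moveprof("class_proportions must have 3 entries (low, medium, high)",
                  "moveprof_config_error")
  }
  if (!is_scalar_number(pause_duration_s) || pause_duration_s <= 0) {
    stop_moveprof("pause_duration_s must be positive", "moveprof_config_error")
  }
  reps <- repetitions_per_movement
  if (is.null(names(reps))) {
    reps <- setNames(rep(as.integer(reps[1]), length(movements)), movements)
  }
  if (any(reps < 1)) {
    stop_moveprof("repetitions_per_movement must be >= 1",
                  "moveprof_config_error")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      movements = movements,
      repetitions_per_movement = reps,
      bilateral = isTRUE(bilateral),
      pause_duration_s = pause_duration_s,
      class_proportions = setNames(as.numeric(class_proportions),
                                   proficiency_grades()),
      overlap = overlap,
      rate_hz = rate_hz,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}
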
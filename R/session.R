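#' Construct an IMU session
#'
#' A session is one subject's recording: thirteen synchronized 9-axis
#' sensors, movement start/end markers, and one gross-competency score per
#' (movement, side). Channels hold tri-axial accelerometer (g), gyroscope
#' (deg/s) and magnetometer (gauss) series on a common time base in seconds.
#'
#' @param subject_id character scalar.
#' @param channels named list, one element per placement in
#'   `body_placements()$site`; each a data frame with columns
#'   `t_s, ax_g, ay_g, az_g, gx_dps, gy_dps, gz_dps, mx_G, my_G, mz_G` and a
#'   `rate_hz` attribute.
#' @param markers tibble with columns `movement`, `side`
#'   (`"left"`/`"right"`/`"na"`), `start_s`, `end_s`.
#' @param scores tibble with columns `movement`, `side`, `value`
#'   (0-5 in steps of 0.5).
#' @param truth optional ground-truth annotations (tibble with per-repetition
#'   boundaries and grades), attached by the synthetic generator.
#' @return validated object of class `imu_session`.
#' @seealso [read_session()], [write_session()], [generate_subject()]
#' @export
imu_session <- function(subject_id, channels, markers, scores, truth = NULL) {
  session <- structure(
    list(
      subject_id = as.character(subject_id),
      channels = channels,
      markers = tibble::as_tibble(markers),
      scores = tibble::as_tibble(scores),
      truth = if (!is.null(truth)) tibble::as_tibble(truth)
    ),
    class = "imu_session"
  )
  validate_session(session)
  session
}

#' Validate an IMU session against its type invariants
#'
#' Checks placement completeness (13 sites), equal channel lengths, monotone
#' time, sensor range limits (+/-4 g, +/-2000 deg/s, +/-1.9 G), marker
#' ordering and non-overlap, score granularity, and that every marker lies
#' within the recorded time base. Violations raise classed errors; nothing
#' is clipped silently.
#'
#' @param session an `imu_session`.
#' @return the session, invisibly.
#' @export
validate_session <- function(session) {
  if (!inherits(session, c("imu_session", "filtered_session"))) {
    stop_moveprof("not an imu_session", "moveprof_format_error")
  }
  if (inherits(session, "filtered_session")) return(invisible(session))
  sites <- body_placements()$site
  missing_sites <- setdiff(sites, names(session$channels))
  if (length(missing_sites) > 0) {
    stop_moveprof(
      paste0("incomplete session: missing placement(s) ",
             paste(missing_sites, collapse = ", ")),
      "moveprof_incomplete_session_error"
    )
  }
  extra <- setdiff(names(session$channels), sites)
  if (length(extra) > 0) {
    stop_moveprof(paste0("unknown placement(s): ", paste(extra, collapse = ", ")),
                  "moveprof_format_error")
  }
  rng <- sensor_ranges()
  lims <- c(ax_g = rng[["accel_g"]], ay_g = rng[["accel_g"]],
            az_g = rng[["accel_g"]],
            gx_dps = rng[["gyro_dps"]], gy_dps = rng[["gyro_dps"]],
            gz_dps = rng[["gyro_dps"]],
            mx_G = rng[["mag_G"]], my_G = rng[["mag_G"]], mz_G = rng[["mag_G"]])
  for (site in sites) {
    ch <- session$channels[[site]]
    cols <- sensor_csv_columns()
    if (!all(cols %in% names(ch))) {
      stop_moveprof(paste0("sensor ", site, ": missing channel column(s)"),
                    "moveprof_format_error")
    }
    lens <- vapply(cols, function(cc) length(ch[[cc]]), integer(1))
    if (length(unique(lens)) != 1) {
      stop_moveprof(paste0("sensor ", site, ": channel arrays differ in length"),
                    "moveprof_format_error")
    }
    if (is.unsorted(ch$t_s, strictly = TRUE)) {
      stop_moveprof(paste0("sensor ", site, ": time base not strictly monotone"),
                    "moveprof_format_error")
    }
    for (cc in names(lims)) {
      bad <- which(abs(ch[[cc]]) > lims[[cc]])
      if (length(bad) > 0) {
        stop_moveprof(
          sprintf("sensor %s: %s out of range at sample %d (|%g| > %g)",
                  site, cc, bad[1], ch[[cc]][bad[1]], lims[[cc]]),
          "moveprof_range_error"
        )
      }
    }
    rate <- ch_rate(ch)
    if (!is_scalar_number(rate) || rate <= 0) {
      stop_moveprof(paste0("sensor ", site, ": invalid rate_hz"),
                    "moveprof_format_error")
    }
  }
  validate_markers(session$markers, session$channels)
  validate_scores(session$scores, session$markers)
  invisible(session)
}

validate_markers <- function(markers, channels = NULL) {
  req <- c("movement", "side", "start_s", "end_s")
  if (!all(req %in% names(markers))) {
    stop_moveprof("markers must have movement, side, start_s, end_s",
                  "moveprof_format_error")
  }
  if (nrow(markers) == 0) return(invisible(markers))
  if (any(markers$start_s >= markers$end_s)) {
    stop_moveprof("marker with start_s >= end_s", "moveprof_marker_error")
  }
  m <- markers[order(markers$start_s), ]
  if (nrow(m) > 1 && any(m$start_s[-1] < m$end_s[-nrow(m)])) {
    stop_moveprof("overlapping movement markers", "moveprof_marker_error")
  }
  if (!is.null(channels)) {
    t_end <- min(vapply(channels, function(ch) max(ch$t_s), numeric(1)))
    t_start <- max(vapply(channels, function(ch) min(ch$t_s), numeric(1)))
    if (any(markers$start_s < t_start) || any(markers$end_s > t_end + 1e-9)) {
      stop_moveprof("marker outside the recorded time base",
                    "moveprof_marker_error")
    }
  }
  invisible(markers)
}

validate_scores <- function(scores, markers = NULL) {
  req <- c("movement", "side", "value")
  if (!all(req %in% names(scores))) {
    stop_moveprof("scores must have movement, side, value",
                  "moveprof_format_error")
  }
  if (nrow(scores) > 0) {
    bad <- scores$value[!score_is_valid(scores$value)]
    if (length(bad) > 0) {
      stop_moveprof(
        sprintf("invalid gross-competency score %g (must be 0-5 in steps of 0.5)",
                bad[1]),
        "moveprof_score_error"
      )
    }
    key <- paste(scores$movement, scores$side)
    if (anyDuplicated(key)) {
      stop_moveprof("more than one score for the same (movement, side)",
                    "moveprof_score_error")
    }
  }
  invisible(scores)
}

score_is_valid <- function(value) {
  is.finite(value) & value >= 0 & value <= 5 &
    abs(value * 2 - round(value * 2)) < 1e-9
}

#' @export
print.imu_session <- function(x, ...) {
  cat("<imu_session> subject", x$subject_id, "\n")
  cat("  sensors:", length(x$channels), "| markers:", nrow(x$markers),
      "| scores:", nrow(x$scores), "\n")
  dur <- max(vapply(x$channels, function(ch) max(ch$t_s), numeric(1)))
  cat("  duration:", round(dur, 1), "s at",
      ch_rate(x$channels[[1]]), "Hz\n")
  if (!is.null(x$truth)) {
    cat("  ground truth:", nrow(x$truth), "repetitions\n")
  }
  invisible(x)
}
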
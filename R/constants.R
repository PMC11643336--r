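#' Body sites, movement labels, and sensor ranges
#'
#' The pipeline assumes a full-body montage of 13 inertial sensors: three on
#' the trunk (chest, abdomen, sacrum) and five bilateral pairs (upper arm,
#' wrist, thigh, shank, ankle). Movements come from a six-item repertoire of
#' Tai Chi-style balance exercises; all but RTP are practiced bilaterally
#' (once with each foot forward).
#'
#' @return `body_placements()` returns a tibble with columns `site` (13
#'   canonical placement labels), `segment` and `side` (`"left"`, `"right"`,
#'   or `"center"`). `movement_labels()` returns the six movement codes.
#' @examples
#' body_placements()
#' movement_labels()
#' @export
body_placements <- function() {
  tibble::tibble(
    site = c(
      "chest", "abdomen", "sacrum",
      "upper_arm_l", "upper_arm_r", "wrist_l", "wrist_r",
      "thigh_l", "thigh_r", "shank_l", "shank_r", "ankle_l", "ankle_r"
    ),
    segment = c(
      "chest", "abdomen", "sacrum",
      rep(c("upper_arm", "wrist", "thigh", "shank", "ankle"), each = 2)
    ),
    side = c(
      rep("center", 3),
      rep(c("left", "right"), times = 5)
    )
  )
}

#' @rdname body_placements
#' @export
movement_labels <- function() {
  c("RTP", "PUSH", "GST", "WHLC", "BKTS", "GR")
}

#' @rdname body_placements
#' @export
sensor_ranges <- function() {
  c(accel_g = 4, gyro_dps = 2000, mag_G = 1.9)
}

#' @rdname body_placements
#' @export
proficiency_grades <- function() {
  c("low", "medium", "high")
}

# movements practiced with both left and right foot forward
bilateral_movements <- function() setdiff(movement_labels(), "RTP")

# canonical per-sensor CSV columns
sensor_csv_columns <- function() {
  c("t_s", "ax_g", "ay_g", "az_g", "gx_dps", "gy_dps", "gz_dps",
    "mx_G", "my_G", "mz_G")
}
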
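#' The default 378-feature registry
#'
#' The feature set has three families and totals 378 entries:
#' \itemize{
#'   \item spectral (312): per sensor (13) x modality (accel, gyro) x axis
#'     (3) x band (lowpass, bandpass) x statistic (dominant frequency,
#'     mean frequency);
#'   \item orientation (52): per sensor (13), mean pitch, mean roll, pitch
#'     range, roll range from the low-pass accelerometer;
#'   \item cross-correlation (14): peak coefficient and signed lag of the
#'     band-pass gyroscope magnitude for 7 sensor pairs emphasizing
#'     ankle-wrist synchrony (R-ankle/R-wrist, R-ankle/L-wrist,
#'     L-ankle/R-wrist, L-ankle/L-wrist, R-ankle/L-ankle, R-wrist/L-wrist,
#'     chest/sacrum).
#' }
#' The registry order is canonical: feature tables are stored and modeled
#' in this order, and a hash of the registry travels with every feature
#' table and model bundle so artifacts from different registries cannot be
#' mixed.
#'
#' @return tibble with columns `name`, `family`, `placement`, `placement_b`
#'   (xcorr only), `modality`, `axis`, `band`, `statistic`.
#' @examples
#' nrow(feature_registry()) # 378
#' @export
feature_registry <- function() {
  sites <- body_placements()$site
  spectral <- tidyr::expand_grid(
    placement = sites,
    modality = c("acc", "gyr"),
    axis = c("x", "y", "z"),
    band = c("lp", "bp"),
    statistic = c("domf", "meanf")
  )
  spectral <- dplyr::mutate(
    spectral,
    family = "spectral", placement_b = NA_character_,
    name = paste("spec", .data$placement, .data$modality, .data$axis,
                 .data$band, .data$statistic, sep = "_")
  )
  orientation <- tidyr::expand_grid(
    placement = sites,
    statistic = c("pitch_mean", "roll_mean", "pitch_range", "roll_range")
  )
  orientation <- dplyr::mutate(
    orientation,
    family = "orientation", placement_b = NA_character_,
    modality = "acc", axis = NA_character_, band = "lp",
    name = paste("ori", .data$placement, .data$statistic, sep = "_")
  )
  pairs <- tibble::tribble(
    ~placement, ~placement_b,
    "ankle_r", "wrist_r",
    "ankle_r", "wrist_l",
    "ankle_l", "wrist_r",
    "ankle_l", "wrist_l",
    "ankle_r", "ankle_l",
    "wrist_r", "wrist_l",
    "chest", "sacrum"
  )
  xcorr <- tidyr::expand_grid(pairs, statistic = c("peak", "lag"))
  xcorr <- dplyr::mutate(
    xcorr,
    family = "xcorr", modality = "gyr", axis = "mag", band = "bp",
    name = paste("xc", .data$placement, .data$placement_b, .data$statistic,
                 sep = "_")
  )
  cols <- c("name", "family", "placement", "placement_b", "modality",
            "axis", "band", "statistic")
  out <- dplyr::bind_rows(spectral[, cols], orientation[, cols],
                          xcorr[, cols])
  stopifnot(!anyDuplicated(out$name))
  out
}

#' @rdname feature_registry
#' @param registry a feature registry tibble.
#' @export
registry_hash <- function(registry = feature_registry()) {
  fnv1a_hash(registry$name)
}

#' Write or read a registry as YAML
#'
#' The registry is data-driven configuration: alternative reconstructions
#' of the feature set can be dropped in as YAML files.
#'
#' @param registry a feature registry tibble.
#' @param path YAML file path.
#' @return `read_registry()` returns a registry tibble.
#' @export
write_registry <- function(registry, path) {
  recs <- lapply(seq_len(nrow(registry)), function(i) {
    r <- as.list(registry[i, ])
    r[!vapply(r, is.na, logical(1))]
  })
  yaml::write_yaml(recs, path)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  recs <- yaml::read_yaml(path)
  cols <- c("name", "family", "placement", "placement_b", "modality",
            "axis", "band", "statistic")
  out <- dplyr::bind_rows(lapply(recs, function(r) {
    r <- modifyList(setNames(as.list(rep(NA_character_, length(cols))), cols),
                    r)
    tibble::as_tibble(r[cols])
  }))
  if (anyDuplicated(out$name)) {
    stop_moveprof("registry has duplicate feature names",
                  "moveprof_schema_error")
  }
  out
}
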
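#' Read and write sessions on disk
#'
#' A session is stored as one CSV per sensor plus a JSON manifest, mirroring
#' per-device logging. The manifest records the subject id, the
#' placement-to-file map, movement markers, gross-competency scores, and
#' (optionally) ground-truth annotations from the synthetic generator.
#' Sensor CSVs have the canonical columns
#' `t_s,ax_g,ay_g,az_g,gx_dps,gy_dps,gz_dps,mx_G,my_G,mz_G`, written with a
#' fixed 6-decimal format so that write-read-write round-trips are
#' byte-identical.
#'
#' @param manifest_path path to a session manifest JSON.
#' @param session an `imu_session`.
#' @param dir output directory (created if needed).
#' @return `read_session()` returns a validated `imu_session`;
#'   `write_session()` returns the manifest path, invisibly.
#' @export
read_session <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop_moveprof(paste0("manifest not found: ", manifest_path),
                  "moveprof_io_error")
  }
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  base <- dirname(manifest_path)
  files <- man$sensors
  if (is.null(files) || is.null(names(files))) {
    stop_moveprof("manifest has no sensor map", "moveprof_format_error")
  }
  channels <- lapply(seq_along(files), function(i) {
    path <- file.path(base, files[[i]])
    if (!file.exists(path)) {
      stop_moveprof(paste0("sensor file not found: ", path), "moveprof_io_error")
    }
    df <- readr::read_csv(path, col_types = readr::cols(.default = "d"),
                          progress = FALSE)
    if (!identical(names(df), sensor_csv_columns())) {
      stop_moveprof(paste0("sensor file ", path, ": unexpected columns"),
                    "moveprof_format_error")
    }
    attr(df, "rate_hz") <- man$rate_hz %||% 100
    df
  })
  names(channels) <- names(files)
  markers <- manifest_tibble(man$markers,
                             c(movement = "character", side = "character",
                               start_s = "numeric", end_s = "numeric"))
  scores <- manifest_tibble(man$scores,
                            c(movement = "character", side = "character",
                              value = "numeric"))
  truth <- if (!is.null(man$truth) && length(man$truth) > 0) {
    tibble::as_tibble(man$truth)
  }
  imu_session(man$subject_id, channels, markers, scores, truth)
}

manifest_tibble <- function(x, proto) {
  if (is.null(x) || length(x) == 0) {
    cols <- lapply(proto, function(tp) vector(tp, 0))
    return(tibble::as_tibble(cols))
  }
  tibble::as_tibble(x)
}

#' @rdname read_session
#' @export
write_session <- function(session, dir) {
  validate_session(session)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sites <- names(session$channels)
  files <- setNames(paste0(sites, ".csv"), sites)
  for (site in sites) {
    ch <- session$channels[[site]]
    write_sensor_csv(ch, file.path(dir, files[[site]]))
  }
  man <- list(
    subject_id = session$subject_id,
    rate_hz = ch_rate(session$channels[[1]]),
    sensors = as.list(files),
    markers = df_to_records(session$markers),
    scores = df_to_records(session$scores),
    truth = df_to_records(session$truth)
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

df_to_records <- function(df) {
  if (is.null(df) || nrow(df) == 0) return(list())
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
}

write_sensor_csv <- function(ch, path) {
  cols <- sensor_csv_columns()
  mat <- vapply(cols, function(cc) sprintf("%.6f", ch[[cc]]),
                character(nrow(ch)))
  lines <- c(paste(cols, collapse = ","),
             apply(matrix(mat, ncol = length(cols)), 1, paste, collapse = ","))
  writeLines(lines, path)
}

#' Read and write per-repetition feature tables
#'
#' Feature tables are CSV files with the label columns
#' `repetition_id, subject_id, movement, side, grade` followed by all
#' registry features in canonical registry order. The registry fingerprint
#' is stored in a header comment; on read, columns are restored to
#' canonical order regardless of on-disk order, and unknown feature columns
#' are rejected.
#'
#' @param features a feature table (tibble) as produced by
#'   [extract_cohort_features()].
#' @param path CSV path.
#' @param registry feature registry (see [feature_registry()]).
#' @return `read_feature_table()` returns the feature table with its
#'   `registry_hash` attribute restored.
#' @export
write_feature_table <- function(features, path,
                                registry = feature_registry()) {
  label_cols <- c("repetition_id", "subject_id", "movement", "side", "grade")
  want <- c(label_cols, registry$name)
  missing_cols <- setdiff(want, names(features))
  if (length(missing_cols) > 0) {
    stop_moveprof(paste0("feature table missing column(s): ",
                         paste(head(missing_cols, 3), collapse = ", ")),
                  "moveprof_schema_error")
  }
  hash <- attr(features, "registry_hash") %||% registry_hash(registry)
  writeLines(paste0("# moveprof feature table; registry_hash=", hash), path)
  readr::write_csv(features[, want], path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path, registry = feature_registry()) {
  if (!file.exists(path)) {
    stop_moveprof(paste0("feature table not found: ", path), "moveprof_io_error")
  }
  first <- readLines(path, n = 1)
  hash <- sub(".*registry_hash=", "", first)
  df <- readr::read_csv(path, comment = "#", progress = FALSE,
                        col_types = readr::cols(
                          repetition_id = "c", subject_id = "c",
                          movement = "c", side = "c", grade = "c",
                          .default = "d"))
  label_cols <- c("repetition_id", "subject_id", "movement", "side", "grade")
  unknown <- setdiff(names(df), c(label_cols, registry$name))
  if (length(unknown) > 0) {
    stop_moveprof(paste0("unknown feature column(s): ",
                         paste(head(unknown, 3), collapse = ", ")),
                  "moveprof_schema_error")
  }
  missing_cols <- setdiff(c(label_cols, registry$name), names(df))
  if (length(missing_cols) > 0) {
    stop_moveprof(paste0("feature table missing column(s): ",
                         paste(head(missing_cols, 3), collapse = ", ")),
                  "moveprof_schema_error")
  }
  out <- df[, c(label_cols, registry$name)] # canonical order restored
  attr(out, "registry_hash") <- hash
  out
}

#' Save and load fitted model bundles
#'
#' A bundle archives a fitted object (movement classifier, proficiency bank,
#' or hierarchical scorer) together with the registry fingerprint it was
#' trained under and its training seed, so scoring can refuse feature tables
#' from a different registry.
#'
#' @param object a fitted moveprof model object.
#' @param path file path (`.rds`).
#' @return `read_model_bundle()` returns the fitted object.
#' @export
write_model_bundle <- function(object, path) {
  saveRDS(object, path, version = 2)
  invisible(path)
}

#' @rdname write_model_bundle
#' @export
read_model_bundle <- function(path) {
  if (!file.exists(path)) {
    stop_moveprof(paste0("model bundle not found: ", path), "moveprof_io_error")
  }
  readRDS(path)
}
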
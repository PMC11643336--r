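test_that("session write-read round-trips with byte-identical CSV payloads", {
  s <- fix_session()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- write_session(s, d1)
  s2 <- read_session(m1)
  expect_equal(s2$subject_id, s$subject_id)
  expect_equal(s2$markers, s$markers)
  expect_equal(s2$scores$value, s$scores$value)
  write_session(s2, d2)
  for (site in names(s$channels)) {
    f1 <- readBin(file.path(d1, paste0(site, ".csv")), "raw", 1e7)
    f2 <- readBin(file.path(d2, paste0(site, ".csv")), "raw", 1e7)
    expect_identical(f1, f2)
  }
})

test_that("incomplete or invalid sessions are rejected, not clipped", {
  s <- fix_session()
  d <- withr::local_tempdir()
  write_session(s, d)
  man <- jsonlite::read_json(file.path(d, "manifest.json"),
                             simplifyVector = TRUE)
  man$sensors$chest <- NULL # 12 sensors
  jsonlite::write_json(man, file.path(d, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  expect_error(read_session(file.path(d, "manifest.json")),
               class = "moveprof_incomplete_session_error")

  bad <- s
  bad$scores$value[1] <- 3.25
  expect_error(validate_session(bad), class = "moveprof_score_error")

  bad2 <- s
  bad2$channels$chest$gx_dps[5] <- 2500
  expect_error(validate_session(bad2), class = "moveprof_range_error")

  bad3 <- s
  bad3$channels$chest$t_s[2] <- bad3$channels$chest$t_s[1]
  expect_error(validate_session(bad3), class = "moveprof_format_error")

  bad4 <- s
  bad4$markers$end_s[1] <- bad4$markers$start_s[1] - 1
  expect_error(validate_session(bad4), class = "moveprof_marker_error")
})

test_that("a session with no markers is still valid on disk", {
  s <- fix_session()
  s$markers <- s$markers[0, ]
  s$scores <- s$scores[0, ]
  s$truth <- NULL
  d <- withr::local_tempdir()
  m <- write_session(s, d)
  s2 <- read_session(m)
  expect_equal(nrow(s2$markers), 0)
})

test_that("feature tables round-trip losslessly with canonical column order", {
  ft <- fix_mini_features()
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ft, path)
  back <- read_feature_table(path)
  expect_equal(names(back), names(ft)[seq_len(ncol(back))])
  expect_equal(as.data.frame(back), as.data.frame(ft), tolerance = 1e-12)
  expect_identical(attr(back, "registry_hash"), registry_hash())

  # permuted on-disk column order is restored to registry order
  lines <- readLines(path)
  header <- strsplit(lines[2], ",")[[1]]
  perm <- c(header[1:5], rev(header[-(1:5)]))
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  readr::write_csv(df[, perm], path)
  writeLines(c(lines[1], readLines(path)), path)
  back2 <- read_feature_table(path)
  expect_equal(names(back2), names(back))
  expect_equal(back2$spec_chest_acc_x_lp_domf, back$spec_chest_acc_x_lp_domf)
})

test_that("empty feature tables and unknown columns are handled", {
  ft <- fix_mini_features()
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ft[0, ], path)
  back <- read_feature_table(path)
  expect_equal(nrow(back), 0)
  expect_equal(ncol(back), 5 + nrow(feature_registry()))

  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  df$not_a_feature <- numeric(0)
  readr::write_csv(df, path)
  expect_error(read_feature_table(path), class = "moveprof_schema_error")
})

test_that("registries round-trip through YAML and fingerprint changes", {
  reg <- feature_registry()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_registry(reg[1:20, ], path)
  back <- read_registry(path)
  expect_equal(back$name, reg$name[1:20])
  expect_false(identical(registry_hash(back), registry_hash(reg)))
})

test_that("model bundles round-trip and keep the registry fingerprint", {
  ft <- fix_mini_features()
  clf <- train_movement_classifier(ft, head(feature_registry()$name, 5),
                                   seed = 1)
  path <- withr::local_tempfile(fileext = ".rds")
  write_model_bundle(clf, path)
  back <- read_model_bundle(path)
  expect_identical(back$features, clf$features)
  expect_identical(back$registry_hash, registry_hash())
})
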
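test_that("gross-competency scores discretize by the documented rule", {
  expect_equal(discretize_score(2.5), "low")
  expect_equal(discretize_score(3.0), "medium")
  expect_equal(discretize_score(4.0), "high")
  expect_equal(discretize_score(c(0, 2.5, 3.5, 5)),
               c("low", "low", "medium", "high"))
  expect_error(discretize_score(3.25), class = "moveprof_score_error")
  expect_error(discretize_score(5.5), class = "moveprof_score_error")
})

curve_evaluator <- function(scores) {
  i <- 0
  function(table, features, label_column, seed) {
    i <<- i + 1
    scores[i]
  }
}

test_that("the 95% rule picks the smallest sufficient k on a given curve", {
  d <- data.frame(movement = rep(c("a", "b"), 10), x1 = 1, x2 = 2, x3 = 3,
                  x4 = 4)
  sel <- select_feature_count(d, paste0("x", 1:4),
                              evaluator = curve_evaluator(
                                c(0.50, 0.80, 0.95, 0.96)),
                              k_grid = 1:4)
  expect_equal(sel$chosen_k, 3) # 0.95 >= 0.95 * 0.96; 0.80 < 0.912
  expect_equal(sel$features, c("x1", "x2", "x3"))

  flat <- select_feature_count(d, paste0("x", 1:4),
                               evaluator = curve_evaluator(
                                 c(0.9, 0.9, 0.9, 0.9)),
                               k_grid = 1:4)
  expect_equal(flat$chosen_k, 1)
})

test_that("the selection invariant holds for arbitrary curves", {
  d <- data.frame(movement = rep(c("a", "b"), 10))
  for (f in paste0("x", 1:12)) d[[f]] <- rnorm(20)
  set.seed(4)
  for (i in 1:10) {
    scores <- sort(runif(12, 0.3, 1)) # monotone curve
    sel <- select_feature_count(d, paste0("x", 1:12),
                                evaluator = curve_evaluator(scores),
                                k_grid = 1:12)
    closed_form <- which(scores >= 0.95 * scores[12])[1]
    expect_equal(sel$chosen_k, closed_form)
    expect_gte(sel$curve[match(sel$chosen_k, sel$k_grid)],
               0.95 * sel$reference_score)
    if (sel$chosen_k > 1) {
      before <- sel$curve[sel$k_grid < sel$chosen_k]
      expect_true(all(before < 0.95 * sel$reference_score))
    }
  }
})

test_that("an evaluator failure aborts with the partial curve attached", {
  d <- data.frame(movement = rep(c("a", "b"), 10), x1 = 1, x2 = 2)
  boom <- function(table, features, label_column, seed) {
    if (length(features) > 1) stop("boom")
    0.5
  }
  err <- tryCatch(
    select_feature_count(d, c("x1", "x2"), evaluator = boom, k_grid = 1:2),
    error = function(e) e
  )
  expect_s3_class(err, "moveprof_selection_error")
  expect_equal(err$partial_curve$score, 0.5)
})

test_that("classifier training is deterministic and validates its inputs", {
  ft <- fix_mini_features()
  feats <- head(feature_registry()$name, 10)
  m1 <- train_movement_classifier(ft, feats, seed = 9)
  m2 <- train_movement_classifier(ft, feats, seed = 9)
  probe <- as.data.frame(ft[1:10, feats])
  expect_identical(as.character(predict(m1$forest, probe)),
                   as.character(predict(m2$forest, probe)))
  expect_equal(m1$forest$ntree, 100)

  single <- ft[ft$movement == "RTP", ]
  expect_error(train_movement_classifier(single, feats),
               class = "moveprof_training_error")
})

test_that("the proficiency bank trains one model per movement", {
  ft <- fix_mini_features()
  bank <- train_proficiency_bank(ft, seed = 3, k_grid = c(2, 5, 10))
  expect_setequal(names(bank$models), unique(ft$movement))
  td <- tidy(bank)
  expect_true(all(td$n_features >= 1))

  # single-grade movement -> degenerate but still present
  ft2 <- ft
  ft2$grade[ft2$movement == "RTP"] <- "high"
  bank2 <- train_proficiency_bank(ft2, seed = 3, k_grid = c(2, 5))
  expect_true(bank2$models$RTP$degenerate)
  pred <- predict(bank2$models$RTP$forest, ft2[1:3, ])
  expect_equal(as.character(pred), rep("high", 3))

  ft3 <- ft
  ft3$grade[1] <- NA
  expect_error(train_proficiency_bank(ft3),
               class = "moveprof_training_error")
})

test_that("the hierarchical scorer routes on predictions, never on truth", {
  ft <- fix_mini_features()
  feats <- head(feature_registry()$name, 10)
  clf <- train_movement_classifier(ft, feats, seed = 1)
  bank <- train_proficiency_bank(ft, seed = 1, k_grid = c(2, 5))
  scorer <- hierarchical_scorer(clf, bank)

  out <- score_repetitions(scorer, ft)
  expect_equal(nrow(out), nrow(ft))
  # routing contract: grade comes from the predicted movement's model
  forced <- score_repetitions(scorer, ft, force_movement = ft$movement)
  direct <- unlist(lapply(unique(ft$movement), function(m) {
    rows <- which(ft$movement == m)
    model <- bank$models[[m]]
    setNames(as.character(predict(model$forest,
                                  as.data.frame(ft[rows, model$features]))),
             rows)
  }))
  expect_equal(forced$pred_grade[as.integer(names(direct))],
               unname(direct))

  # deliberate misrouting still yields a grade from the wrong bank model
  wrong <- score_repetitions(scorer, ft[1:5, ], force_movement = "GST")
  expect_equal(wrong$pred_movement, rep("GST", 5))
  expect_true(all(wrong$pred_grade %in% proficiency_grades()))

  expect_equal(nrow(score_repetitions(scorer, ft[0, ])), 0)
})

test_that("registry fingerprints guard the scorer", {
  ft <- fix_mini_features()
  feats <- head(feature_registry()$name, 10)
  clf <- train_movement_classifier(ft, feats, seed = 1)
  bank <- train_proficiency_bank(ft, seed = 1, k_grid = c(2, 5))
  scorer <- hierarchical_scorer(clf, bank)
  alien <- ft
  attr(alien, "registry_hash") <- "deadbeef"
  expect_error(score_repetitions(scorer, alien),
               class = "moveprof_registry_error")
})

test_that("majority vote equals exhaustive mode counting with low tie-break", {
  expect_equal(aggregate_majority(c("high", "high", "high")), "high")
  expect_equal(aggregate_majority(c("low", "low", "high", "medium")), "low")
  expect_equal(aggregate_majority(c("low", "low", "high", "high")), "low")
  expect_error(aggregate_majority(character(0)),
               class = "moveprof_parameter_error")

  # all multisets of size <= 9 against exhaustive counting
  grades <- proficiency_grades()
  set.seed(5)
  for (i in 1:200) {
    g <- sample(grades, sample(1:9, 1), replace = TRUE)
    counts <- vapply(grades, function(x) sum(g == x), integer(1))
    winners <- grades[counts == max(counts)]
    expect_equal(aggregate_majority(g), winners[1]) # lowest wins ties
  }
})
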
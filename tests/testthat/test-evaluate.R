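test_that("micro F1 is pooled accuracy for single-label multiclass", {
  expect_equal(micro_f1(c("a", "b"), c("a", "b")), 1)
  truth <- c(rep("a", 4), rep("b", 3), rep("c", 3))
  pred <- truth
  pred[c(1, 5, 9)] <- c("b", "c", "a")
  expect_equal(micro_f1(truth, pred), 0.7)
  expect_equal(micro_f1(rep(c("a", "b", "c"), 4), rep("a", 12)), 1 / 3)
  expect_error(micro_f1("a", c("a", "b")), class = "moveprof_parameter_error")

  set.seed(6)
  for (i in 1:20) {
    t <- sample(letters[1:4], 50, replace = TRUE)
    p <- sample(letters[1:4], 50, replace = TRUE)
    expect_equal(micro_f1(t, p), mean(t == p))
  }
})

test_that("LOSO plans hold every subject out exactly once per repeat", {
  subs <- sprintf("P%02d", 1:32)
  plan <- make_loso_plan(subs, n_repeats = 20, seed = 1)
  expect_equal(nrow(plan), 640)
  for (r in c(1, 20)) {
    expect_setequal(plan$holdout_subject[plan$repeat_idx == r], subs)
  }
  # repeats differ only through seeds; folds deterministic
  expect_equal(length(unique(plan$seed)), 20)
  plan2 <- make_loso_plan(subs, n_repeats = 20, seed = 1)
  expect_identical(plan, plan2)

  expect_equal(nrow(make_loso_plan(c("a", "b"), 1, 1)), 2)
  expect_error(make_loso_plan("a", 1, 1), class = "moveprof_parameter_error")
  expect_error(make_loso_plan(c("a", "a"), 1, 1),
               class = "moveprof_parameter_error")
})

test_that("confusion matrices are coherent with the metrics derived from them", {
  truth <- c("a", "a", "b", "b", "c", "c")
  pred <- c("a", "b", "b", "b", "c", "a")
  cm <- confusion_matrix(truth, pred)
  expect_equal(unname(rowSums(cm)), c(2, 2, 2))
  expect_equal(sum(diag(cm)) / sum(cm), micro_f1(truth, pred))
  metrics <- class_metrics(cm)
  expect_equal(metrics$recall, c(0.5, 1, 0.5))
  # empty predicted class reported as 0 with a flag, not NaN
  cm2 <- confusion_matrix(c("a", "b"), c("a", "a"), levels = c("a", "b"))
  m2 <- class_metrics(cm2)
  expect_equal(m2$precision[m2$class == "b"], 0)
  expect_true(m2$undefined_precision[m2$class == "b"])
})

test_that("movement evaluation on a small cohort is reproducible", {
  ft <- fix_mini_features()
  r1 <- evaluate_movement_id(ft, n_repeats = 2, seed = 3,
                             k_grid = c(2, 5, 10), mrmr_max_rank = 15,
                             evaluator = grouped_cv_evaluator(3, 30, 1))
  r2 <- evaluate_movement_id(ft, n_repeats = 2, seed = 3,
                             k_grid = c(2, 5, 10), mrmr_max_rank = 15,
                             evaluator = grouped_cv_evaluator(3, 30, 1))
  expect_identical(r1$per_repeat, r2$per_repeat)
  expect_identical(r1$confusion, r2$confusion)
  expect_equal(sum(r1$confusion), nrow(ft) * 2)
  # two distinct archetypes separate well even at this scale
  expect_gt(r1$micro_f1_mean, 0.8)
  expect_equal(glance(r1)$micro_f1_mean, r1$micro_f1_mean)
})

test_that("no held-out subject leaks into training or selection", {
  ft <- fix_mini_features()
  seen <- new.env()
  ev <- function(table, features, label_column, seed) {
    assign(paste0("s", length(ls(seen))), unique(table$subject_id),
           envir = seen)
    0.9
  }
  r <- evaluate_movement_id(ft, n_repeats = 1, seed = 3, k_grid = c(2, 5),
                            mrmr_max_rank = 5, evaluator = ev)
  holdouts <- sort(unique(ft$subject_id))
  for (nm in ls(seen)) {
    expect_lt(length(get(nm, envir = seen)), length(holdouts))
  }
  # predictions cover every subject exactly once per repeat
  expect_setequal(unique(r$predictions$subject_id), holdouts)
})

test_that("a single-repeat evaluation reports zero spread", {
  ft <- fix_mini_features()
  r <- evaluate_movement_id(ft, n_repeats = 1, seed = 3, k_grid = c(2, 5),
                            mrmr_max_rank = 10,
                            evaluator = grouped_cv_evaluator(3, 30, 1))
  expect_equal(r$micro_f1_sd, 0)
})

test_that("Sammon projection recovers exact embeddings and beats PCA stress", {
  set.seed(7)
  flat <- cbind(matrix(rnorm(40), 20, 2))
  p <- sammon_project(flat, target_dim = 2)
  expect_lt(p$stress, 1e-6)
  d0 <- as.numeric(dist(flat))
  d1 <- as.numeric(dist(p$coords))
  expect_equal(d1, d0, tolerance = 1e-3)

  tetra <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
                 c(0.5, sqrt(3) / 6, sqrt(6) / 3))
  expect_gt(sammon_project(tetra, target_dim = 2)$stress, 1e-4)

  cloud <- matrix(rnorm(100), 20, 5)
  pr <- sammon_project(cloud, target_dim = 2)
  expect_lte(pr$stress, pr$stress_initial)
  pr3 <- sammon_project(cloud, target_dim = 3)
  expect_lte(pr3$stress, pr$stress)

  dup <- rbind(cloud, cloud[1, , drop = FALSE])
  pd <- sammon_project(dup, target_dim = 2, seed = 1)
  expect_true(pd$duplicates_flag)
  expect_error(sammon_project(matrix(1:4, 2, 2), target_dim = 3),
               class = "moveprof_parameter_error")
})

test_that("tidiers and plots cover the main result types", {
  ft <- fix_mini_features()
  sel <- select_feature_count(ft, head(feature_registry()$name, 6),
                              evaluator = grouped_cv_evaluator(3, 20, 1),
                              k_grid = c(2, 4), label_column = "movement")
  expect_s3_class(autoplot(sel), "ggplot")
  expect_equal(nrow(tidy(sel)), length(sel$k_grid))
  expect_equal(glance(sel)$chosen_k, sel$chosen_k)

  pr <- sammon_project(as.matrix(ft[1:15, 6:20]), target_dim = 2)
  expect_s3_class(autoplot(pr, labels = ft$movement[1:15]), "ggplot")
  expect_equal(nrow(tidy(pr)), 15)
})
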
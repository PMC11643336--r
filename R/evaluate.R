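#' Leave-one-subject-out cross-validation plan
#'
#' Every subject is held out exactly once per repeat; repeats differ only
#' through the training seed handed to the models (the folds themselves
#' are deterministic), which is what produces the run-to-run spread
#' reported with LOSO-repeat evaluations. Repeat seeds are derived
#' deterministically from the master seed.
#'
#' @param subjects character vector of subject ids (>= 2, unique).
#' @param n_repeats number of repeats (the reference protocol used 20).
#' @param seed master seed.
#' @return a `loso_plan`: tibble with `repeat_idx`, `fold`,
#'   `holdout_subject`, `seed`.
#' @examples
#' make_loso_plan(c("S1", "S2", "S3"), n_repeats = 2, seed = 1)
#' @export
make_loso_plan <- function(subjects, n_repeats = 20, seed = 1L) {
  if (anyDuplicated(subjects)) {
    stop_moveprof("duplicate subject ids", "moveprof_parameter_error")
  }
  if (length(subjects) < 2) {
    stop_moveprof("LOSO needs at least 2 subjects", "moveprof_parameter_error")
  }
  repeat_seeds <- derive_seeds(seed, n_repeats)
  plan <- tidyr::expand_grid(repeat_idx = seq_len(n_repeats),
                             fold = seq_along(subjects))
  plan$holdout_subject <- subjects[plan$fold]
  plan$seed <- repeat_seeds[plan$repeat_idx]
  structure(plan, class = c("loso_plan", class(plan)))
}

#' Micro-averaged F1 score
#'
#' F1 computed from pooled true/false positives across classes; for
#' single-label multiclass prediction this equals plain accuracy.
#'
#' @param truth,predicted equal-length label vectors.
#' @return fraction in `[0, 1]`.
#' @examples
#' micro_f1(c("a", "b", "b"), c("a", "b", "a"))
#' @export
micro_f1 <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop_moveprof("truth and predicted must have equal length",
                  "moveprof_parameter_error")
  }
  if (length(truth) == 0) {
    stop_moveprof("micro F1 of an empty label set is undefined",
                  "moveprof_parameter_error")
  }
  mean(as.character(truth) == as.character(predicted))
}

#' Pooled confusion matrix and per-class metrics
#'
#' @param truth,predicted label vectors.
#' @param levels class order (default: union, sorted).
#' @return `confusion_matrix()` returns a square table (rows = truth);
#'   `class_metrics()` a tibble of per-class precision/recall, with
#'   undefined values (empty class) reported as 0 and flagged.
#' @export
confusion_matrix <- function(truth, predicted, levels = NULL) {
  levels <- levels %||% sort(union(unique(truth), unique(predicted)))
  table(truth = factor(truth, levels = levels),
        predicted = factor(predicted, levels = levels))
}

#' @rdname confusion_matrix
#' @param cm a confusion matrix from `confusion_matrix()`.
#' @export
class_metrics <- function(cm) {
  tp <- diag(cm)
  pred_n <- colSums(cm)
  true_n <- rowSums(cm)
  tibble::tibble(
    class = rownames(cm),
    precision = unname(ifelse(pred_n > 0, tp / pred_n, 0)),
    recall = unname(ifelse(true_n > 0, tp / true_n, 0)),
    undefined_precision = unname(pred_n == 0),
    undefined_recall = unname(true_n == 0),
    n_true = unname(as.integer(true_n))
  )
}

# internal: run one LOSO pass of movement classification, returning
# per-repetition predictions for all folds of one repeat
loso_movement_pass <- function(features, plan_rows, selection_mode,
                               global_selection, k_grid, mrmr_max_rank,
                               ntree, evaluator) {
  preds <- vector("list", nrow(plan_rows))
  for (i in seq_len(nrow(plan_rows))) {
    holdout <- plan_rows$holdout_subject[i]
    seed_i <- plan_rows$seed[i] + plan_rows$fold[i]
    train <- features[features$subject_id != holdout, ]
    test <- features[features$subject_id == holdout, ]
    if (nrow(test) == 0) next
    sel <- if (selection_mode == "nested") {
      ranking <- mrmr_rank(train, "movement", max_rank = mrmr_max_rank)
      select_feature_count(train, ranking, evaluator = evaluator,
                           label_column = "movement",
                           k_grid = k_grid, seed = seed_i)
    } else {
      global_selection
    }
    clf <- train_movement_classifier(train, sel, seed = seed_i, ntree = ntree)
    x <- as.data.frame(test[, clf$features, drop = FALSE])
    preds[[i]] <- tibble::tibble(
      repetition_id = test$repetition_id,
      subject_id = test$subject_id,
      movement = test$movement,
      grade = test$grade,
      pred_movement = as.character(predict(clf$forest, x)),
      chosen_k = length(clf$features)
    )
  }
  dplyr::bind_rows(preds)
}

#' Evaluate movement identification under repeated LOSO
#'
#' For every repeat and fold, feature selection (mRMR ranking + the
#' 95%-of-full-set rule) and Random Forest training happen inside the
#' training subjects only (`selection = "nested"`, the default), or once
#' on the full table (`selection = "paper"`, which reproduces selection
#' protocols that precede the cross-validation and accepts the leakage
#' that implies). Per-repeat micro F1 is aggregated to mean and SD, and
#' the pooled confusion matrix and per-class metrics are reported.
#'
#' @param features cohort feature table from [extract_cohort_features()].
#' @param n_repeats LOSO repeats.
#' @param seed master seed.
#' @param selection `"nested"` or `"paper"`.
#' @param k_grid,mrmr_max_rank selection economy knobs, see
#'   [select_feature_count()] and [mrmr_rank()].
#' @param ntree trees per forest.
#' @return an `evaluation_report`.
#' @export
evaluate_movement_id <- function(features, n_repeats = 3, seed = 1L,
                                 selection = c("nested", "paper"),
                                 k_grid = NULL, mrmr_max_rank = 40,
                                 ntree = 100, evaluator = NULL) {
  selection <- match.arg(selection)
  if (is.null(k_grid)) k_grid <- c(1:8, 10, 12, 15, 20, 30)
  # the 6-class task warrants a low-noise selection curve: more splits and
  # trees than the per-movement graders need
  if (is.null(evaluator)) evaluator <- grouped_cv_evaluator(3, 80, 4)
  subjects <- sort(unique(features$subject_id))
  plan <- make_loso_plan(subjects, n_repeats, seed)
  global_sel <- NULL
  if (selection == "paper") {
    ranking <- mrmr_rank(features, "movement", max_rank = mrmr_max_rank)
    global_sel <- select_feature_count(features, ranking,
                                       evaluator = evaluator,
                                       label_column = "movement",
                                       k_grid = k_grid, seed = seed)
  }
  per_repeat <- vector("list", n_repeats)
  all_preds <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    rows <- plan[plan$repeat_idx == r, ]
    preds <- loso_movement_pass(features, rows, selection, global_sel,
                                k_grid, mrmr_max_rank, ntree, evaluator)
    all_preds[[r]] <- dplyr::mutate(preds, repeat_idx = r)
    per_repeat[[r]] <- tibble::tibble(
      repeat_idx = r,
      micro_f1 = micro_f1(preds$movement, preds$pred_movement),
      mean_chosen_k = mean(preds$chosen_k)
    )
  }
  preds <- dplyr::bind_rows(all_preds)
  per_repeat <- dplyr::bind_rows(per_repeat)
  cm <- confusion_matrix(preds$movement, preds$pred_movement,
                         levels = sort(unique(features$movement)))
  structure(
    list(
      task = "movement",
      per_repeat = per_repeat,
      micro_f1_mean = mean(per_repeat$micro_f1),
      micro_f1_sd = if (n_repeats > 1) sd(per_repeat$micro_f1) else 0,
      confusion = cm,
      class_metrics = class_metrics(cm),
      predictions = preds,
      config = list(n_repeats = n_repeats, seed = seed,
                    selection = selection, ntree = ntree)
    ),
    class = "evaluation_report"
  )
}

#' Evaluate proficiency assessment under repeated LOSO
#'
#' Per movement, a 3-class proficiency forest (with its own nested feature
#' selection) is trained on the training subjects and applied to the
#' held-out subject's repetitions of that movement. Two scores are
#' reported per movement: the repetitions micro F1 (per-repetition
#' predictions) and the overall micro F1 (one majority-vote grade per
#' subject-movement). A unified model pooled over all movements is
#' evaluated the same way for comparison.
#'
#' @inheritParams evaluate_movement_id
#' @param unified also fit and report the unified (all-movements) model.
#' @return an `evaluation_report` with `per_movement`, `unified`, and
#'   pooled prediction tables.
#' @export
evaluate_proficiency <- function(features, n_repeats = 3, seed = 1L,
                                 k_grid = NULL, mrmr_max_rank = 40,
                                 ntree = 100, unified = TRUE,
                                 evaluator = grouped_cv_evaluator(3, 50, 2)) {
  subjects <- sort(unique(features$subject_id))
  plan <- make_loso_plan(subjects, n_repeats, seed)
  if (is.null(k_grid)) k_grid <- c(1:10, 15, 20, 30)
  movements <- sort(unique(features$movement))
  all_preds <- list()
  all_uni <- list()
  excluded <- character(0)
  for (r in seq_len(n_repeats)) {
    rows <- plan[plan$repeat_idx == r, ]
    for (i in seq_len(nrow(rows))) {
      holdout <- rows$holdout_subject[i]
      seed_i <- rows$seed[i] + rows$fold[i]
      train <- features[features$subject_id != holdout, ]
      test <- features[features$subject_id == holdout, ]
      if (nrow(test) == 0) {
        excluded <- c(excluded, holdout)
        next
      }
      bank <- train_proficiency_bank(train, seed = seed_i, ntree = ntree,
                                     k_grid = k_grid,
                                     mrmr_max_rank = mrmr_max_rank,
                                     evaluator = evaluator)
      for (m in intersect(movements, unique(test$movement))) {
        model <- bank$models[[m]]
        tm <- test[test$movement == m, ]
        xm <- as.data.frame(tm[, model$features, drop = FALSE])
        all_preds[[length(all_preds) + 1L]] <- tibble::tibble(
          repeat_idx = r, repetition_id = tm$repetition_id,
          subject_id = tm$subject_id, movement = m,
          grade = tm$grade,
          pred_grade = as.character(predict(model$forest, xm))
        )
      }
      if (unified) {
        uni <- train_unified_proficiency(train, seed = seed_i,
                                         k_grid = k_grid,
                                         mrmr_max_rank = mrmr_max_rank,
                                         evaluator = evaluator)
        xu <- as.data.frame(test[, uni$features, drop = FALSE])
        all_uni[[length(all_uni) + 1L]] <- tibble::tibble(
          repeat_idx = r, repetition_id = test$repetition_id,
          subject_id = test$subject_id, movement = test$movement,
          grade = test$grade,
          pred_grade = as.character(predict(uni$forest, xu))
        )
      }
    }
  }
  preds <- dplyr::bind_rows(all_preds)
  summarize_scores <- function(df) {
    rep_scores <- df |>
      dplyr::group_by(.data$repeat_idx) |>
      dplyr::summarise(
        rep_f1 = micro_f1(.data$grade, .data$pred_grade),
        .groups = "drop"
      )
    overall_scores <- df |>
      dplyr::group_by(.data$repeat_idx, .data$subject_id, .data$movement) |>
      dplyr::summarise(
        grade = .data$grade[1],
        pred = aggregate_majority(.data$pred_grade),
        .groups = "drop"
      ) |>
      dplyr::group_by(.data$repeat_idx) |>
      dplyr::summarise(
        overall_f1 = micro_f1(.data$grade, .data$pred),
        .groups = "drop"
      )
    list(
      rep_f1_mean = mean(rep_scores$rep_f1),
      rep_f1_sd = if (nrow(rep_scores) > 1) sd(rep_scores$rep_f1) else 0,
      overall_f1_mean = mean(overall_scores$overall_f1),
      overall_f1_sd = if (nrow(overall_scores) > 1) {
        sd(overall_scores$overall_f1)
      } else 0
    )
  }
  per_movement <- dplyr::bind_rows(lapply(movements, function(m) {
    s <- summarize_scores(preds[preds$movement == m, ])
    tibble::tibble(movement = m, rep_f1_mean = s$rep_f1_mean,
                   rep_f1_sd = s$rep_f1_sd,
                   overall_f1_mean = s$overall_f1_mean,
                   overall_f1_sd = s$overall_f1_sd)
  }))
  pooled <- summarize_scores(preds)
  uni_preds <- dplyr::bind_rows(all_uni)
  uni_summary <- if (unified && nrow(uni_preds) > 0) {
    summarize_scores(uni_preds)
  }
  cm <- confusion_matrix(preds$grade, preds$pred_grade,
                         levels = proficiency_grades())
  structure(
    list(
      task = "proficiency",
      per_movement = per_movement,
      pooled = pooled,
      unified = uni_summary,
      confusion = cm,
      class_metrics = class_metrics(cm),
      predictions = preds,
      unified_predictions = uni_preds,
      excluded_subjects = unique(excluded),
      config = list(n_repeats = n_repeats, seed = seed, ntree = ntree)
    ),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>", x$task, "\n")
  if (x$task == "movement") {
    cat(sprintf("  micro F1: %.2f%% +/- %.2f%% over %d repeat(s)\n",
                100 * x$micro_f1_mean, 100 * x$micro_f1_sd,
                nrow(x$per_repeat)))
  } else {
    cat(sprintf("  repetitions micro F1 (pooled): %.2f%%\n",
                100 * x$pooled$rep_f1_mean))
    cat(sprintf("  overall micro F1 (pooled): %.2f%%\n",
                100 * x$pooled$overall_f1_mean))
    if (!is.null(x$unified)) {
      cat(sprintf("  unified model repetitions micro F1: %.2f%%\n",
                  100 * x$unified$rep_f1_mean))
    }
  }
  invisible(x)
}

#' Misrouting robustness of the hierarchical cascade
#'
#' Repetitions misclassified by the movement-identification stage are
#' routed to the wrong movement's proficiency model; this analysis counts,
#' for each (true movement, predicted movement) pair, how often the wrong
#' model still produces the correct grade.
#'
#' @param features cohort feature table.
#' @param seed master seed.
#' @param k_grid,mrmr_max_rank,ntree as in [evaluate_movement_id()].
#' @return list with `counts` (tibble: true movement, predicted movement,
#'   n misrouted, n grade-correct), `n_misrouted`, `n_correct`, and the
#'   per-repetition `predictions`.
#' @export
misrouting_robustness <- function(features, seed = 1L, k_grid = NULL,
                                  mrmr_max_rank = 40, ntree = 100) {
  subjects <- sort(unique(features$subject_id))
  plan <- make_loso_plan(subjects, n_repeats = 1, seed = seed)
  if (is.null(k_grid)) k_grid <- c(1:10, 15, 20, 30)
  preds <- list()
  for (i in seq_len(nrow(plan))) {
    holdout <- plan$holdout_subject[i]
    seed_i <- plan$seed[i] + plan$fold[i]
    train <- features[features$subject_id != holdout, ]
    test <- features[features$subject_id == holdout, ]
    if (nrow(test) == 0) next
    ranking <- mrmr_rank(train, "movement", max_rank = mrmr_max_rank)
    sel <- select_feature_count(train, ranking, label_column = "movement",
                                k_grid = k_grid, seed = seed_i)
    clf <- train_movement_classifier(train, sel, seed = seed_i, ntree = ntree)
    bank <- train_proficiency_bank(train, seed = seed_i, ntree = ntree,
                                   k_grid = k_grid,
                                   mrmr_max_rank = mrmr_max_rank)
    scorer <- hierarchical_scorer(clf, bank)
    p <- score_repetitions(scorer, test)
    p$grade <- test$grade
    preds[[length(preds) + 1L]] <- p
  }
  preds <- dplyr::bind_rows(preds)
  mis <- preds[preds$pred_movement != preds$movement, ]
  counts <- if (nrow(mis) == 0) {
    tibble::tibble(movement = character(), pred_movement = character(),
                   n = integer(), n_correct = integer())
  } else {
    mis |>
      dplyr::group_by(.data$movement, .data$pred_movement) |>
      dplyr::summarise(
        n = dplyr::n(),
        n_correct = sum(.data$pred_grade == .data$grade),
        .groups = "drop"
      )
  }
  list(
    counts = counts,
    n_misrouted = nrow(mis),
    n_correct = sum(counts$n_correct),
    predictions = preds
  )
}
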
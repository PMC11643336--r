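#' Discretize gross-competency scores into proficiency grades
#'
#' Scores run 0-5 in steps of 0.5; grades are `low` below 3, `medium` in
#' `[3, 4)`, and `high` at 4 and above.
#'
#' @param value numeric score(s).
#' @return character grades.
#' @examples
#' discretize_score(c(2.5, 3, 4))
#' @export
discretize_score <- function(value) {
  bad <- value[!score_is_valid(value)]
  if (length(bad) > 0) {
    stop_moveprof(
      sprintf("invalid score %g (must be 0-5 in steps of 0.5)", bad[1]),
      "moveprof_score_error"
    )
  }
  ifelse(value < 3, "low", ifelse(value < 4, "medium", "high"))
}

#' Choose the number of features by the 95%-of-full-set rule
#'
#' Given an mRMR ranking, a model is evaluated with an increasing number of
#' top-ranked features; the chosen count is the smallest `k` whose score
#' reaches `threshold` (default 95%) of the score with the largest
#' evaluated set. The score curve may be evaluated on a sub-grid of `k`
#' values for economy; the reference score is always the largest `k`.
#'
#' Because the curve is estimated by cross-validation on a handful of
#' subjects, raw scores fluctuate by a few percent between adjacent `k`;
#' a spurious upward fluctuation at small `k` would otherwise truncate the
#' feature set prematurely. Under an mRMR ordering, adding features never
#' genuinely reduces achievable accuracy, so by default the curve is
#' regularized to be non-decreasing (isotonic regression) before the rule
#' is applied; `monotone = FALSE` uses the raw curve.
#'
#' @param table labeled feature table (training data only).
#' @param ranking character vector from [mrmr_rank()].
#' @param evaluator `function(table, features, label_column, seed) ->
#'   micro F1`; the default is a subject-grouped 3-fold cross-validation
#'   (see [grouped_cv_evaluator()]).
#' @param threshold fraction of the full-set score to reach (default 0.95).
#' @param k_grid increasing integer vector of candidate counts; defaults
#'   to `1..min(K, 30)` plus `K`.
#' @param label_column class-label column.
#' @param seed seed passed to the evaluator.
#' @param monotone regularize the score curve to be non-decreasing before
#'   applying the rule (default `TRUE`).
#' @return a `selection_result`: list with `ranking`, `k_grid`, `curve`
#'   (the curve the rule was applied to), `raw_curve`, `chosen_k`,
#'   `features` (the chosen head of the ranking), `threshold`,
#'   `reference_score`, `seed`.
#' @export
select_feature_count <- function(table, ranking,
                                 evaluator = grouped_cv_evaluator(),
                                 threshold = 0.95, k_grid = NULL,
                                 label_column = "movement", seed = 1L,
                                 monotone = TRUE) {
  K <- length(ranking)
  if (is.null(k_grid)) k_grid <- seq_len(min(K, 30L))
  # the largest evaluated set is always the full ranking: the 95% rule is
  # anchored to the full-set score
  k_grid <- sort(unique(c(pmin(as.integer(k_grid), K), K)))
  curve <- numeric(length(k_grid))
  for (i in seq_along(k_grid)) {
    res <- tryCatch(
      evaluator(table, ranking[seq_len(k_grid[i])], label_column, seed),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      abort(
        paste0("evaluator failed at k = ", k_grid[i], ": ",
               conditionMessage(res)),
        class = c("moveprof_selection_error", "moveprof_error"),
        partial_curve = tibble::tibble(k = k_grid[seq_len(i - 1)],
                                       score = curve[seq_len(i - 1)])
      )
    }
    curve[i] <- res
  }
  raw_curve <- curve
  if (monotone && length(curve) > 1) {
    curve <- stats::isoreg(seq_along(curve), curve)$yf
  }
  reference <- curve[length(curve)]
  ok <- curve >= threshold * reference
  chosen_k <- k_grid[which(ok)[1]]
  structure(
    list(
      ranking = ranking,
      k_grid = k_grid,
      curve = curve,
      raw_curve = raw_curve,
      chosen_k = chosen_k,
      features = ranking[seq_len(chosen_k)],
      threshold = threshold,
      reference_score = reference,
      seed = seed
    ),
    class = "selection_result"
  )
}

# out-of-bag micro F1 of a 100-tree forest (within-subject estimate)
oob_evaluator <- function(table, features, label_column, seed) {
  fit <- fit_forest(table, features, label_column, seed)
  micro_f1(table[[label_column]], as.character(fit$predicted))
}

#' Subject-grouped cross-validation evaluator for feature selection
#'
#' The selection curve must estimate generalization to new subjects, so the
#' default evaluator scores each candidate feature count by k-fold
#' cross-validation with whole subjects assigned to folds (never split
#' across train and validation). Out-of-bag estimates, which mix a
#' subject\'s repetitions across trees, systematically overstate small
#' feature sets; the grouped evaluator does not. Falls back to the
#' out-of-bag estimate when the table has no `subject_id` or fewer
#' subjects than folds.
#'
#' @param n_folds subject folds (default 3).
#' @param ntree trees per evaluation forest (smaller than the final model
#'   for economy).
#' @return an evaluator `function(table, features, label_column, seed)`
#'   for [select_feature_count()].
#' @export
grouped_cv_evaluator <- function(n_folds = 3, ntree = 60, n_splits = 3) {
  force(n_folds)
  force(ntree)
  force(n_splits)
  function(table, features, label_column, seed) {
    subjects <- unique(table$subject_id)
    if (is.null(subjects) || length(subjects) < n_folds) {
      fit <- fit_forest(table, features, label_column, seed, ntree = ntree)
      return(micro_f1(table[[label_column]], as.character(fit$predicted)))
    }
    scores <- vapply(seq_len(n_splits), function(sp) {
      grouped_cv_once(table, features, label_column, seed + sp - 1L,
                      subjects, n_folds, ntree)
    }, numeric(1))
    mean(scores)
  }
}

grouped_cv_once <- function(table, features, label_column, seed, subjects,
                            n_folds, ntree) {
    fold_of <- with_seed(seed, {
      setNames(sample(rep_len(seq_len(n_folds), length(subjects))), subjects)
    })
    truth <- character(0)
    pred <- character(0)
    for (f in seq_len(n_folds)) {
      va <- table$subject_id %in% subjects[fold_of[subjects] == f]
      if (!any(va) || all(va)) next
      tr_tab <- table[!va, ]
      # a validation class missing from training still counts as an error;
      # a training class with a single row cannot be fitted, so fall back
      # to the in-sample estimate (rare, tiny folds only)
      if (any(table(tr_tab[[label_column]]) < 2)) {
        fit <- fit_forest(table, features, label_column, seed, ntree = ntree)
        return(micro_f1(table[[label_column]], as.character(fit$predicted)))
      }
      fit <- fit_forest(tr_tab, features, label_column, seed, ntree = ntree)
      x <- as.data.frame(table[va, features, drop = FALSE])
      truth <- c(truth, table[[label_column]][va])
      pred <- c(pred, as.character(predict(fit, x)))
    }
    micro_f1(truth, pred)
}

fit_forest <- function(table, features, label_column, seed, ntree = 100) {
  y <- factor(table[[label_column]])
  if (any(table(y) < 2)) {
    low <- names(which(table(y) < 2))
    stop_moveprof(paste0("class with fewer than 2 samples: ",
                         paste(low, collapse = ", ")),
                  "moveprof_training_error")
  }
  x <- as.data.frame(table[, features, drop = FALSE])
  with_seed(seed, randomForest::randomForest(x, y, ntree = ntree))
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result>", length(x$ranking), "features ranked;",
      "chosen_k =", x$chosen_k, "\n")
  cat("  reference score:", round(x$reference_score, 4),
      "| threshold:", x$threshold, "\n")
  invisible(x)
}

#' Train the movement-identification classifier
#'
#' A 100-tree Random Forest on the selected features, with out-of-bag
#' micro F1 recorded. Left and right variants of a movement are one class;
#' side stays metadata.
#'
#' @param feature_table labeled feature table (training rows only).
#' @param selection a `selection_result` computed on the training rows, or
#'   a character vector of feature names.
#' @param seed training seed.
#' @param ntree number of trees.
#' @return a `movement_classifier`: forest, features, classes, OOB
#'   micro F1, seed, registry hash.
#' @export
train_movement_classifier <- function(feature_table, selection, seed = 1L,
                                      ntree = 100) {
  features <- selection_features(selection)
  if (length(unique(feature_table$movement)) < 2) {
    stop_moveprof("movement classifier needs at least 2 movements",
                  "moveprof_training_error")
  }
  fit <- fit_forest(feature_table, features, "movement", seed, ntree)
  structure(
    list(
      forest = fit,
      features = features,
      classes = levels(fit$y),
      oob_micro_f1 = micro_f1(as.character(fit$y),
                              as.character(fit$predicted)),
      seed = seed,
      registry_hash = attr(feature_table, "registry_hash")
    ),
    class = "movement_classifier"
  )
}

selection_features <- function(selection) {
  if (inherits(selection, "selection_result")) selection$features
  else as.character(selection)
}

#' @export
print.movement_classifier <- function(x, ...) {
  cat("<movement_classifier>", length(x$classes), "movements,",
      length(x$features), "features, OOB micro F1 =",
      round(x$oob_micro_f1, 4), "\n")
  invisible(x)
}

#' Train the per-movement proficiency model bank
#'
#' One 3-class (low/medium/high) forest per movement, each with its own
#' feature selection; class imbalance is left as observed (no resampling
#' or reweighting). A movement whose training data shows a single grade is
#' still trained but flagged degenerate.
#'
#' @param feature_table labeled table with a `grade` column.
#' @param selections named list movement -> `selection_result` or feature
#'   vector; `NULL` entries (or a `NULL` list) trigger in-place mRMR +
#'   95%-rule selection per movement.
#' @param seed training seed.
#' @param ntree trees per forest.
#' @param k_grid selection grid forwarded to [select_feature_count()].
#' @param mrmr_max_rank forwarded to [mrmr_rank()].
#' @param evaluator selection-curve evaluator, see [grouped_cv_evaluator()].
#' @return a `proficiency_bank`: named list of per-movement models plus
#'   metadata.
#' @export
train_proficiency_bank <- function(feature_table, selections = NULL,
                                   seed = 1L, ntree = 100, k_grid = NULL,
                                   mrmr_max_rank = 40,
                                   evaluator = grouped_cv_evaluator()) {
  if (!"grade" %in% names(feature_table) ||
      any(is.na(feature_table$grade))) {
    stop_moveprof("feature table must carry a grade for every repetition",
                  "moveprof_training_error")
  }
  movements <- sort(unique(feature_table$movement))
  models <- vector("list", length(movements))
  names(models) <- movements
  for (m in movements) {
    sub <- feature_table[feature_table$movement == m, ]
    degenerate <- length(unique(sub$grade)) < 2
    sel <- selections[[m]]
    if (is.null(sel)) {
      if (degenerate) {
        sel <- head(names(sub)[vapply(sub, is.numeric, logical(1))], 10)
      } else {
        ranking <- mrmr_rank(sub, "grade", max_rank = mrmr_max_rank)
        sel <- select_feature_count(sub, ranking, evaluator = evaluator,
                                    label_column = "grade",
                                    k_grid = k_grid, seed = seed)
      }
    }
    features <- selection_features(sel)
    fit <- if (degenerate) {
      constant_model(unique(sub$grade))
    } else {
      fit_forest(sub, features, "grade", seed, ntree)
    }
    models[[m]] <- list(
      movement = m,
      forest = fit,
      features = features,
      selection = if (inherits(sel, "selection_result")) sel,
      degenerate = degenerate
    )
  }
  structure(
    list(
      models = models,
      seed = seed,
      registry_hash = attr(feature_table, "registry_hash")
    ),
    class = "proficiency_bank"
  )
}

constant_model <- function(grade) {
  structure(list(grade = grade), class = "constant_grade_model")
}

#' @export
predict.constant_grade_model <- function(object, newdata, ...) {
  factor(rep(object$grade, nrow(newdata)), levels = proficiency_grades())
}

#' @export
print.proficiency_bank <- function(x, ...) {
  cat("<proficiency_bank>", length(x$models), "movement model(s)\n")
  for (m in names(x$models)) {
    cat("  ", m, ": ", length(x$models[[m]]$features), " features",
        if (x$models[[m]]$degenerate) " [degenerate]", "\n", sep = "")
  }
  invisible(x)
}

#' Train a unified proficiency model
#'
#' A single 3-class forest over all movements pooled, used as the
#' comparison point for the movement-specific bank.
#'
#' @inheritParams train_proficiency_bank
#' @return a `unified_proficiency_model`.
#' @export
train_unified_proficiency <- function(feature_table, selection = NULL,
                                      seed = 1L, ntree = 100, k_grid = NULL,
                                      mrmr_max_rank = 40,
                                      evaluator = grouped_cv_evaluator()) {
  if (is.null(selection)) {
    ranking <- mrmr_rank(feature_table, "grade", max_rank = mrmr_max_rank)
    selection <- select_feature_count(feature_table, ranking,
                                      evaluator = evaluator,
                                      label_column = "grade",
                                      k_grid = k_grid, seed = seed)
  }
  features <- selection_features(selection)
  fit <- fit_forest(feature_table, features, "grade", seed)
  structure(
    list(forest = fit, features = features,
         selection = if (inherits(selection, "selection_result")) selection,
         seed = seed,
         registry_hash = attr(feature_table, "registry_hash")),
    class = "unified_proficiency_model"
  )
}

#' Assemble the hierarchical scorer
#'
#' Movement identification routes each repetition to that movement's
#' proficiency model (routing always uses the predicted movement, never
#' the truth), and per-(subject, movement) grades are aggregated by
#' majority vote.
#'
#' @param movement_model a `movement_classifier`.
#' @param bank a `proficiency_bank`.
#' @return a `hierarchical_scorer`.
#' @export
hierarchical_scorer <- function(movement_model, bank) {
  if (!is.null(movement_model$registry_hash) &&
      !is.null(bank$registry_hash) &&
      !identical(movement_model$registry_hash, bank$registry_hash)) {
    stop_moveprof("movement model and bank come from different registries",
                  "moveprof_registry_error")
  }
  structure(
    list(movement_model = movement_model, bank = bank,
         registry_hash = movement_model$registry_hash %||% bank$registry_hash),
    class = "hierarchical_scorer"
  )
}

#' Score repetitions through the hierarchical cascade
#'
#' @param scorer a `hierarchical_scorer`.
#' @param feature_table repetitions to score (same registry as training).
#' @param force_movement optional character vector overriding the movement
#'   routing (used by consistency checks); `NULL` routes on predictions.
#' @return tibble: `repetition_id`, `subject_id`, `movement` (truth, if
#'   present), `pred_movement`, `pred_grade`.
#' @export
score_repetitions <- function(scorer, feature_table, force_movement = NULL) {
  if (nrow(feature_table) == 0) {
    return(tibble::tibble(repetition_id = character(),
                          subject_id = character(), movement = character(),
                          pred_movement = character(),
                          pred_grade = character()))
  }
  tab_hash <- attr(feature_table, "registry_hash")
  if (!is.null(tab_hash) && !is.null(scorer$registry_hash) &&
      !identical(tab_hash, scorer$registry_hash)) {
    stop_moveprof("feature table registry does not match the scorer",
                  "moveprof_registry_error")
  }
  mm <- scorer$movement_model
  x <- as.data.frame(feature_table[, mm$features, drop = FALSE])
  pred_movement <- if (is.null(force_movement)) {
    as.character(predict(mm$forest, x))
  } else {
    rep_len(as.character(force_movement), nrow(feature_table))
  }
  pred_grade <- character(nrow(feature_table))
  for (m in unique(pred_movement)) {
    rows <- which(pred_movement == m)
    model <- scorer$bank$models[[m]]
    if (is.null(model)) {
      stop_moveprof(paste0("no proficiency model for movement ", m),
                    "moveprof_routing_error")
    }
    xm <- as.data.frame(feature_table[rows, model$features, drop = FALSE])
    pred_grade[rows] <- as.character(predict(model$forest, xm))
  }
  col_or <- function(nm, default) {
    if (nm %in% names(feature_table)) feature_table[[nm]] else default
  }
  tibble::tibble(
    repetition_id = col_or("repetition_id",
                           sprintf("rep%04d", seq_len(nrow(feature_table)))),
    subject_id = col_or("subject_id", NA_character_),
    movement = col_or("movement", NA_character_),
    pred_movement = pred_movement,
    pred_grade = pred_grade
  )
}

#' Majority-vote aggregation of repetition grades
#'
#' The overall grade for a (subject, movement) is the modal repetition
#' grade; ties break toward the lower grade (conservative for a
#' balance-training context).
#'
#' @param grades character vector of repetition grades (non-empty).
#' @return single grade.
#' @examples
#' aggregate_majority(c("low", "low", "high", "high")) # "low"
#' @export
aggregate_majority <- function(grades) {
  if (length(grades) == 0) {
    stop_moveprof("cannot aggregate an empty set of grades",
                  "moveprof_parameter_error")
  }
  order_g <- proficiency_grades() # low < medium < high
  counts <- table(factor(grades, levels = order_g))
  winners <- names(counts)[counts == max(counts)]
  winners[1] # levels are ordered low, medium, high: first is lowest
}
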
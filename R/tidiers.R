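#' Tidy and glance methods for fitted moveprof objects
#'
#' Broom-style accessors: `tidy()` returns the per-unit breakdown of an
#' object as a tibble, `glance()` a one-row model summary.
#'
#' @param x a `selection_result`, `movement_classifier`,
#'   `proficiency_bank`, `evaluation_report`, or `sammon_projection`.
#' @param ... unused.
#' @return a tibble.
#' @name moveprof-tidiers
NULL

#' @rdname moveprof-tidiers
#' @method tidy selection_result
#' @export
tidy.selection_result <- function(x, ...) {
  tibble::tibble(
    k = x$k_grid,
    score = x$curve,
    chosen = x$k_grid == x$chosen_k
  )
}

#' @rdname moveprof-tidiers
#' @method glance selection_result
#' @export
glance.selection_result <- function(x, ...) {
  tibble::tibble(
    chosen_k = x$chosen_k,
    reference_score = x$reference_score,
    threshold = x$threshold,
    n_ranked = length(x$ranking)
  )
}

#' @rdname moveprof-tidiers
#' @method tidy movement_classifier
#' @export
tidy.movement_classifier <- function(x, ...) {
  imp <- randomForest::importance(x$forest)
  tibble::tibble(
    feature = rownames(imp),
    importance = as.numeric(imp[, 1])
  )
}

#' @rdname moveprof-tidiers
#' @method glance movement_classifier
#' @export
glance.movement_classifier <- function(x, ...) {
  tibble::tibble(
    n_classes = length(x$classes),
    n_features = length(x$features),
    ntree = x$forest$ntree,
    oob_micro_f1 = x$oob_micro_f1,
    seed = x$seed
  )
}

#' @rdname moveprof-tidiers
#' @method tidy proficiency_bank
#' @export
tidy.proficiency_bank <- function(x, ...) {
  dplyr::bind_rows(lapply(x$models, function(m) {
    tibble::tibble(
      movement = m$movement,
      n_features = length(m$features),
      degenerate = m$degenerate,
      chosen_k = if (!is.null(m$selection)) m$selection$chosen_k else NA_integer_
    )
  }))
}

#' @rdname moveprof-tidiers
#' @method glance proficiency_bank
#' @export
glance.proficiency_bank <- function(x, ...) {
  tibble::tibble(
    n_movements = length(x$models),
    n_degenerate = sum(vapply(x$models, function(m) m$degenerate, logical(1))),
    seed = x$seed
  )
}

#' @rdname moveprof-tidiers
#' @method tidy evaluation_report
#' @export
tidy.evaluation_report <- function(x, ...) {
  if (x$task == "movement") {
    x$class_metrics
  } else {
    x$per_movement
  }
}

#' @rdname moveprof-tidiers
#' @method glance evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) {
  if (x$task == "movement") {
    tibble::tibble(
      micro_f1_mean = x$micro_f1_mean,
      micro_f1_sd = x$micro_f1_sd,
      n_repeats = x$config$n_repeats
    )
  } else {
    tibble::tibble(
      rep_f1_mean = x$pooled$rep_f1_mean,
      rep_f1_sd = x$pooled$rep_f1_sd,
      overall_f1_mean = x$pooled$overall_f1_mean,
      overall_f1_sd = x$pooled$overall_f1_sd,
      unified_rep_f1_mean = if (!is.null(x$unified)) {
        x$unified$rep_f1_mean
      } else NA_real_,
      n_repeats = x$config$n_repeats
    )
  }
}

#' @rdname moveprof-tidiers
#' @method tidy sammon_projection
#' @export
tidy.sammon_projection <- function(x, ...) {
  coords <- tibble::as_tibble(x$coords, .name_repair = "minimal")
  names(coords) <- paste0("dim", seq_len(ncol(coords)))
  coords
}

#' @rdname moveprof-tidiers
#' @method glance sammon_projection
#' @export
glance.sammon_projection <- function(x, ...) {
  tibble::tibble(
    stress = x$stress,
    stress_initial = x$stress_initial,
    duplicates_flag = x$duplicates_flag
  )
}
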
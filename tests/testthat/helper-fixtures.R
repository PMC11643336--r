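# shared fixtures, built once per test run and memoized

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# one subject, two movements, high grade
fix_session <- function() {
  memo("session", {
    cfg <- cohort_config(n_subjects = 2, movements = c("RTP", "GST"),
                         seed = 11)
    generate_subject(movement_archetypes(), c(RTP = "high", GST = "high"),
                     cfg, seed = 7, subject_id = "S01")
  })
}

fix_filtered <- function() {
  memo("filtered", preprocess_session(fix_session()))
}

# small 3-subject, 2-movement cohort and its feature table
fix_mini_cohort <- function() {
  memo("mini_cohort", {
    generate_cohort(cohort_config(n_subjects = 3,
                                  movements = c("RTP", "GST"),
                                  seed = 21))
  })
}

fix_mini_features <- function() {
  memo("mini_features", extract_cohort_features(fix_mini_cohort()$sessions))
}

# independent brute-force mRMR (MID) oracle: own discretization + MI via
# table(), greedy search by exhaustive score evaluation
oracle_discretize <- function(x, bins = 3) {
  br <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1),
                        names = FALSE))
  if (length(br) < 2) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = br, include.lowest = TRUE, labels = FALSE))
}

oracle_mi <- function(x, y) {
  jt <- table(x, y)
  p <- jt / sum(jt)
  px <- rowSums(p)
  py <- colSums(p)
  s <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0) s <- s + p[i, j] * log(p[i, j] / (px[i] * py[j]))
    }
  }
  unname(s)
}

oracle_mrmr <- function(table, label_column, bins = 3) {
  y <- as.integer(factor(table[[label_column]]))
  features <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                      label_column)
  disc <- lapply(features, function(f) oracle_discretize(table[[f]], bins))
  names(disc) <- features
  relevance <- vapply(features, function(f) oracle_mi(disc[[f]], y),
                      numeric(1))
  selected <- character(0)
  remaining <- features
  while (length(remaining) > 0) {
    score <- vapply(remaining, function(f) {
      red <- if (length(selected) == 0) 0 else {
        mean(vapply(selected, function(s) oracle_mi(disc[[f]], disc[[s]]),
                    numeric(1)))
      }
      relevance[[f]] - red
    }, numeric(1))
    pick <- remaining[which.max(score)]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  selected
}
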
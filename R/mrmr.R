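#' Minimum-redundancy maximum-relevance feature ranking
#'
#' Greedy mRMR with the additive MID criterion: features are discretized
#' into equal-frequency bins (default 3), the first pick maximizes mutual
#' information with the label, and each subsequent pick maximizes
#' `I(x; y) - mean(I(x; x_s))` over the already-selected set. The ranking
#' is deterministic given the table: ties are broken by canonical column
#' order. Constant features carry zero relevance and zero redundancy, so
#' they sink to the bottom of the ranking rather than being dropped.
#'
#' @param table data frame containing `label_column` and the candidate
#'   feature columns.
#' @param label_column name of the class-label column.
#' @param features candidate feature names (default: all numeric columns
#'   except the label).
#' @param bins number of equal-frequency bins for discretization.
#' @param max_rank stop the greedy search after this many picks and append
#'   the remaining features in relevance order (the tail of an mRMR ranking
#'   is never used by the selection rule; `Inf` ranks everything greedily).
#' @return character vector of feature names, best first.
#' @examples
#' set.seed(1)
#' d <- data.frame(y = rep(c("a", "b"), 50), x1 = rnorm(100))
#' d$x2 <- as.numeric(d$y == "a") + rnorm(100, sd = 0.1)
#' mrmr_rank(d, "y")[1] # "x2"
#' @export
mrmr_rank <- function(table, label_column, features = NULL, bins = 3,
                      max_rank = Inf) {
  if (!label_column %in% names(table)) {
    stop_moveprof(paste0("label column not found: ", label_column),
                  "moveprof_parameter_error")
  }
  y <- as.integer(factor(table[[label_column]]))
  if (length(unique(y)) < 2) {
    stop_moveprof("mRMR needs at least 2 classes", "moveprof_parameter_error")
  }
  if (is.null(features)) {
    features <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                        label_column)
  }
  if (length(features) < 1) {
    stop_moveprof("mRMR needs at least 1 feature", "moveprof_parameter_error")
  }
  if (length(features) == 1) return(features)
  disc <- vapply(features, function(f) discretize_ef(table[[f]], bins),
                 integer(nrow(table)))
  ny <- max(y)
  relevance <- batch_mi(disc, y, bins, ny)
  names(relevance) <- features
  n_greedy <- min(length(features), max_rank)
  selected <- integer(0)
  remaining <- seq_along(features)
  red_sum <- numeric(length(features))
  for (step in seq_len(n_greedy)) {
    score <- relevance[remaining] -
      if (step == 1) 0 else red_sum[remaining] / length(selected)
    pick <- remaining[which.max(score)]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    if (length(remaining) == 0) break
    red_new <- batch_mi(disc[, remaining, drop = FALSE], disc[, pick],
                        bins, bins)
    red_sum[remaining] <- red_sum[remaining] + red_new
  }
  ranked <- features[selected]
  if (length(remaining) > 0) {
    rest <- features[remaining]
    ranked <- c(ranked, rest[order(-relevance[rest])])
  }
  ranked
}

# equal-frequency discretization into `bins` levels (1-based); constant
# columns map to a single level
discretize_ef <- function(x, bins = 3) {
  if (all(!is.finite(x)) || diff(range(x, finite = TRUE)) < 1e-300) {
    return(rep(1L, length(x)))
  }
  br <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1),
                        na.rm = TRUE, names = FALSE))
  if (length(br) < 2) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = br, include.lowest = TRUE, labels = FALSE))
}

# mutual information (nats) of each column of D with y, via joint tabulation
batch_mi <- function(D, y, nx, ny) {
  n <- length(y)
  hy <- entropy_counts(tabulate(y, ny), n)
  apply_cols <- function(d) {
    joint <- tabulate((d - 1L) * ny + y, nx * ny)
    hx <- entropy_counts(tabulate(d, nx), n)
    hxy <- entropy_counts(joint, n)
    hx + hy - hxy
  }
  if (is.matrix(D)) {
    vapply(seq_len(ncol(D)), function(j) apply_cols(D[, j]), numeric(1))
  } else {
    apply_cols(D)
  }
}

entropy_counts <- function(counts, n) {
  p <- counts[counts > 0] / n
  -sum(p * log(p))
}

#' Mutual information between two discrete vectors
#'
#' Exposed for oracle-style verification of the mRMR implementation.
#'
#' @param x,y integer or factor vectors of equal length.
#' @return mutual information in nats.
#' @export
mutual_information <- function(x, y) {
  x <- as.integer(factor(x))
  y <- as.integer(factor(y))
  batch_mi(matrix(x, ncol = 1), y, max(x), max(y))
}
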
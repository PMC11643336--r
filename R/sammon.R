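#' Sammon projection of a feature matrix
#'
#' Nonlinear mapping to 2 or 3 dimensions minimizing Sammon stress
#' `E = (1 / sum d_ij) * sum (d_ij - D_ij)^2 / d_ij`, where `d_ij` are
#' input-space distances and `D_ij` projected distances. The descent
#' starts from the PCA projection and uses Sammon's iterative scheme with
#' step halving (via [MASS::sammon()]), so the final stress never exceeds
#' the stress of the PCA initialization. Duplicate points (zero pairwise
#' distance) are epsilon-regularized and flagged.
#'
#' @param x numeric matrix or feature tibble (numeric columns are used).
#' @param target_dim 2 or 3.
#' @param seed used only to jitter exactly coincident points.
#' @param max_iter,tol descent controls.
#' @return a `sammon_projection`: list with `coords` (n x target_dim),
#'   `stress`, `stress_initial`, `duplicates_flag`.
#' @examples
#' p <- sammon_project(matrix(rnorm(60), 20, 3), target_dim = 2)
#' p$stress <= p$stress_initial
#' @export
sammon_project <- function(x, target_dim = 2, seed = 1L, max_iter = 500,
                           tol = 1e-6) {
  if (!target_dim %in% c(2, 3)) {
    stop_moveprof("target_dim must be 2 or 3", "moveprof_parameter_error")
  }
  if (is.data.frame(x)) {
    x <- as.matrix(x[vapply(x, is.numeric, logical(1))])
  }
  if (nrow(x) < target_dim + 1) {
    stop_moveprof("need at least target_dim + 1 points",
                  "moveprof_parameter_error")
  }
  d <- dist(x)
  dup_flag <- any(d < 1e-12)
  if (dup_flag) {
    eps <- max(d) * 1e-6 + 1e-12
    jit <- with_seed(seed, matrix(stats::rnorm(length(x), 0, eps), nrow(x)))
    x <- x + jit
    d <- dist(x)
    d[d < eps] <- eps
  }
  # PCA initialization (centered scores on the leading components)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k_avail <- ncol(pc$x)
  init <- pc$x[, seq_len(min(target_dim, k_avail)), drop = FALSE]
  if (ncol(init) < target_dim) {
    init <- cbind(init, matrix(0, nrow(x), target_dim - ncol(init)))
  }
  # break exact ties in the initial configuration (sammon requires
  # distinct starting points)
  if (any(dist(init) < 1e-12)) {
    init <- init + with_seed(seed, matrix(stats::rnorm(length(init),
                                                       0, max(d) * 1e-6),
                                          nrow(init)))
  }
  stress_init <- sammon_stress(d, dist(init))
  fit <- MASS::sammon(d, y = init, k = target_dim, niter = max_iter,
                      tol = tol, trace = FALSE)
  final <- sammon_stress(d, dist(fit$points))
  if (final > stress_init) {
    # descent never accepted a step; keep the initialization
    fit$points <- init
    final <- stress_init
  }
  structure(
    list(coords = fit$points, stress = final, stress_initial = stress_init,
         duplicates_flag = dup_flag),
    class = "sammon_projection"
  )
}

#' Sammon stress between two distance sets
#'
#' @param d input-space distances (`dist` or numeric vector).
#' @param D projected distances, same order.
#' @return the stress value.
#' @export
sammon_stress <- function(d, D) {
  d <- as.numeric(d)
  D <- as.numeric(D)
  keep <- d > 0
  sum((d[keep] - D[keep])^2 / d[keep]) / sum(d[keep])
}

#' @export
print.sammon_projection <- function(x, ...) {
  cat("<sammon_projection>", nrow(x$coords), "points in", ncol(x$coords),
      "dimensions; stress =", signif(x$stress, 4), "\n")
  invisible(x)
}
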
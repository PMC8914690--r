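# Neighborhood component analysis in its diagonal feature-weighting form,
# with the weighted L1 distance that matches the pipeline's 1-NN, and the
# iterative prefix sweep (INCA) that picks the loss-minimizing subset size.

# per-feature absolute-difference matrices, chunked to limit peak memory:
# a list of (n^2) x |chunk| matrices
abs_diff_chunks <- function(X, chunk = 512L) {
  n <- nrow(X)
  p <- ncol(X)
  ii <- rep(seq_len(n), times = n)
  jj <- rep(seq_len(n), each = n)
  starts <- seq(1L, p, by = chunk)
  lapply(starts, function(s) {
    cols <- s:min(s + chunk - 1L, p)
    abs(X[ii, cols, drop = FALSE] - X[jj, cols, drop = FALSE])
  })
}

#' NCA feature weights
#'
#' Learns nonnegative per-feature relevance weights by maximizing the
#' leave-one-out stochastic nearest-neighbour objective
#' `mean_i sum_{j : y_j = y_i} p_ij - lambda * mean(w^2)` with
#' `p_ij = exp(-d_ij / sigma) / sum_l exp(-d_il / sigma)` and the weighted
#' L1 distance `d_ij = sum_k w_k^2 |x_ik - x_jk|`. Optimized by full-batch
#' gradient ascent with backtracking step control; the kernel width `sigma`
#' defaults to the mean initial pairwise distance so the soft-neighbour
#' probabilities are well scaled regardless of dimension. The ridge penalty
#' acts on the mean squared weight so that its per-feature gradient stays
#' commensurate with the per-feature gradient of the neighbour term at any
#' dimensionality.
#'
#' @param X numeric matrix (observations x features).
#' @param y labels with at least two classes.
#' @param lambda ridge penalty (default `1 / nrow(X)`).
#' @param iterations gradient-ascent budget (default 100).
#' @param sigma kernel width, or `NULL` for the automatic choice.
#' @param seed seed for the small symmetric jitter on the initial weights.
#' @param tol relative objective tolerance for early stopping.
#' @param chunk feature-chunk size bounding peak memory.
#' @return Numeric vector of `ncol(X)` nonnegative weights.
#' @export
nca_weights <- function(X, y, lambda = NULL, iterations = 100L, sigma = NULL,
                        seed = 0L, tol = 1e-8, chunk = 512L) {
  X <- as.matrix(X)
  y <- as.factor(y)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 2) stop("at least two observations are required")
  if (nlevels(droplevels(y)) < 2) stop("labels must cover at least 2 classes")
  if (is.null(lambda)) lambda <- 1 / n
  A <- abs_diff_chunks(X, chunk)
  same <- matrix(as.numeric(outer(y, y, `==`)), n, n)
  diag(same) <- 0
  col_of <- rep(seq_along(A), times = vapply(A, ncol, integer(1)))
  dist_for <- function(w2) {
    d <- numeric(n * n)
    for (ci in seq_along(A))
      d <- d + as.numeric(A[[ci]] %*% w2[col_of == ci])
    matrix(d, n, n)
  }
  w <- with_seed(seed, 1 + stats::runif(p, -1e-6, 1e-6))
  if (is.null(sigma)) {
    D0 <- dist_for(w^2)
    sigma <- mean(D0[upper.tri(D0)])
    if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  }
  objective <- function(w) {
    D <- dist_for(w^2)
    K <- exp(-D / sigma)
    diag(K) <- 0
    denom <- rowSums(K)
    denom[denom == 0] <- .Machine$double.eps
    P <- K / denom
    list(value = mean(rowSums(P * same)) - lambda * mean(w^2), P = P)
  }
  ob <- objective(w)
  step <- 1
  for (it in seq_len(iterations)) {
    P <- ob$P
    pin <- rowSums(P * same)
    # C_ij = p_ij * (p_i - same_ij); gradient of the soft-LOO term
    C <- P * (pin - same)
    cvec <- as.numeric(C)
    g <- numeric(p)
    for (ci in seq_along(A))
      g[col_of == ci] <- as.numeric(crossprod(A[[ci]], cvec))
    grad <- (2 * w / (sigma * n)) * g - 2 * lambda * w / p
    improved <- FALSE
    for (bt in 1:30) {
      w_new <- w + step * grad
      ob_new <- objective(w_new)
      if (ob_new$value > ob$value) { improved <- TRUE; break }
      step <- step / 2
    }
    if (!improved) break
    delta <- ob_new$value - ob$value
    w <- w_new
    ob <- ob_new
    step <- step * 1.2
    if (delta < tol * max(abs(ob$value), 1)) break
  }
  abs(w)
}

#' Iterative NCA feature selection (INCA)
#'
#' Ranks the features by [nca_weights()] and sweeps prefix sizes over
#' `size_range` (clipped to `[1, p]`; when the lower bound exceeds `p` the
#' sweep starts at 1). Each prefix is scored by stratified k-fold
#' cross-validated misclassification with the requested classifier; the
#' returned subset is the argmin of the loss curve (ties favour the
#' smaller size).
#'
#' @param X numeric feature matrix.
#' @param y labels.
#' @param size_range two integers `c(lower, upper)` (default `c(100, 512)`).
#' @param classifier `"knn"` or `"svm"`.
#' @param folds CV folds (default 10).
#' @param seed seed for folds and the NCA jitter.
#' @param stride step of the size sweep (default 1; larger values trade
#'   resolution for speed).
#' @param nca_iterations passed to [nca_weights()].
#' @return An object of class `"inca_result"`: `ranking`, `sizes`,
#'   `loss_curve`, `selected_size`, `selected_indices`, `selected_loss`,
#'   `weights`.
#' @export
inca_select <- function(X, y, size_range = c(100L, 512L),
                        classifier = c("knn", "svm"), folds = 10L, seed = 0L,
                        stride = 1L, nca_iterations = 100L) {
  classifier <- match.arg(classifier)
  X <- as.matrix(X)
  p <- ncol(X)
  stopifnot(length(size_range) == 2L, size_range[1] <= size_range[2],
            stride >= 1)
  w <- nca_weights(X, y, iterations = nca_iterations, seed = seed)
  ranking <- order(w, decreasing = TRUE)
  hi <- min(size_range[2], p)
  lo <- max(size_range[1], 1L)
  if (lo > hi) lo <- 1L  # range beyond dimensionality: sweep [1, p]
  sizes <- unique(c(seq(lo, hi, by = stride), hi))
  spec <- classifier_spec(classifier)
  fold_id_seed <- seed  # same folds for every size
  loss_curve <- vapply(sizes, function(s) {
    crossval_loss(X[, ranking[seq_len(s)], drop = FALSE], y, spec,
                  folds, fold_id_seed)
  }, numeric(1))
  best <- which.min(loss_curve)  # which.min takes the first (smallest size)
  structure(list(ranking = ranking, sizes = sizes, loss_curve = loss_curve,
                 selected_size = sizes[best],
                 selected_indices = ranking[seq_len(sizes[best])],
                 selected_loss = loss_curve[best], weights = w,
                 classifier = classifier),
            class = "inca_result")
}

#' @export
print.inca_result <- function(x, ...) {
  cat(sprintf("INCA: %d sizes swept in [%d, %d]; selected %d features (%s loss %.4f)\n",
              length(x$sizes), min(x$sizes), max(x$sizes), x$selected_size,
              x$classifier, x$selected_loss))
  invisible(x)
}
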
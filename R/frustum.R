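# Frustum pattern: a graph-based local ternary texture extractor. Each
# 49-sample window is laid out row-major on a 7x7 grid; three 6-edge directed
# graphs (bottom hexagon, top hexagon, bottom-top connections) compare pairs
# of grid cells through an upper and a lower ternary kernel, giving six 6-bit
# codes per window and six 64-bin histograms per signal (384 features).

# edge lists, 1-based (row, col) pairs on the 7x7 grid, in fixed order
frustum_edges <- function() {
  to_idx <- function(m) (m[, 1] - 1L) * 7L + m[, 2]  # row-major cell index
  bottom <- rbind(c(1,2), c(1,6), c(4,7), c(7,6), c(7,2), c(4,1))
  top    <- rbind(c(2,3), c(2,5), c(4,6), c(6,5), c(6,3), c(4,2))
  b <- to_idx(bottom); t <- to_idx(top)
  ring <- function(v) cbind(a = v, s = c(v[-1], v[1]))  # closed hexagon walk
  list(bottom = ring(b), top = ring(t), connection = cbind(a = b, s = t))
}

#' Ternary threshold for the frustum pattern
#'
#' Half the sample standard deviation of the whole signal. The threshold is
#' global to the signal (or subband), not per window.
#'
#' @param signal numeric vector, length >= 2.
#' @param sd_type `"sample"` (n - 1 denominator, default) or `"population"`.
#' @return Nonnegative scalar threshold.
#' @export
compute_threshold <- function(signal, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (!is.numeric(signal) || length(signal) < 2 || anyNA(signal))
    stop("`signal` must be numeric of length >= 2 with no NA")
  s <- stats::sd(signal)
  if (sd_type == "population") s <- s * sqrt((length(signal) - 1) / length(signal))
  s / 2
}

#' Upper and lower ternary bits
#'
#' The upper kernel fires when `a - s > d`, the lower when `a - s < -d`;
#' both are 0 on the closed band `[-d, d]`.
#'
#' @param a,s numeric vectors (recycled together).
#' @param d nonnegative threshold.
#' @return A list with integer vectors `upper` and `lower`.
#' @export
ternary_bits <- function(a, s, d) {
  stopifnot(d >= 0)
  diff <- a - s
  list(upper = as.integer(diff > d), lower = as.integer(diff < -d))
}

#' Overlapping 49-sample blocks
#'
#' Stride-1 windows: block `i` holds samples `i..i+48`; there are
#' `length(signal) - 48` blocks.
#'
#' @param signal numeric vector, length >= 49.
#' @return A 49-row matrix, one column per block.
#' @export
extract_blocks <- function(signal) {
  L <- length(signal)
  if (L < 49) stop(sprintf("signal has %d samples; at least 49 are required", L))
  n <- L - 48L
  matrix(signal[outer(1:49, 0:(n - 1L), `+`)], nrow = 49L)
}

#' Reshape one block to its 7x7 matrix
#'
#' Row-major fill: `mat[k, l] = block[(k - 1) * 7 + l]`.
#'
#' @param block numeric vector of exactly 49 values.
#' @return A 7x7 numeric matrix.
#' @export
block_to_matrix <- function(block) {
  if (length(block) != 49) stop("a block must contain exactly 49 samples")
  matrix(block, nrow = 7, ncol = 7, byrow = TRUE)
}

#' Encode one 7x7 matrix with the frustum graphs
#'
#' Applies the upper (kernel 1) and lower (kernel 2) ternary comparators to
#' the six directed edges of each graph and packs the bits with weights
#' `2^(j-1)` (edge 1 = least significant bit).
#'
#' @param mat a 7x7 numeric matrix.
#' @param d nonnegative threshold.
#' @return Integer vector `c(b1, b2, t1, t2, c1, c2)`, each in `0..63`.
#' @export
encode_matrix <- function(mat, d) {
  stopifnot(is.matrix(mat), all(dim(mat) == c(7, 7)))
  x <- as.vector(t(mat))  # row-major cell index
  edges <- frustum_edges()
  w <- 2^(0:5)
  out <- integer(6)
  i <- 1L
  for (g in edges) {
    bits <- ternary_bits(x[g[, "a"]], x[g[, "s"]], d)
    out[i] <- sum(bits$upper * w)
    out[i + 1L] <- sum(bits$lower * w)
    i <- i + 2L
  }
  names(out) <- c("b1", "b2", "t1", "t2", "c1", "c2")
  out
}

#' Map signals of the frustum pattern
#'
#' Slides the 49-sample window over the signal (stride 1) and encodes every
#' window with [encode_matrix()], using the signal-global threshold
#' `compute_threshold(signal)`. Vectorized over windows.
#'
#' @param signal numeric vector, length >= 49.
#' @inheritParams compute_threshold
#' @return A list of six integer vectors (`b1`, `b2`, `t1`, `t2`, `c1`,
#'   `c2`), each of length `length(signal) - 48`, values in `0..63`.
#' @export
map_signals <- function(signal, sd_type = "sample") {
  L <- length(signal)
  if (L < 49) stop(sprintf("signal has %d samples; at least 49 are required", L))
  d <- compute_threshold(signal, sd_type)
  n <- L - 48L
  starts <- 0:(n - 1L)
  edges <- frustum_edges()
  w <- 2^(0:5)
  out <- vector("list", 6L)
  i <- 1L
  for (g in edges) {
    up <- integer(n)
    lo <- integer(n)
    for (j in 1:6) {
      diff <- signal[starts + g[j, "a"]] - signal[starts + g[j, "s"]]
      up <- up + as.integer(diff > d) * w[j]
      lo <- lo + as.integer(diff < -d) * w[j]
    }
    out[[i]] <- up
    out[[i + 1L]] <- lo
    i <- i + 2L
  }
  names(out) <- c("b1", "b2", "t1", "t2", "c1", "c2")
  out
}

#' Frustum pattern feature vector
#'
#' Histograms (64 integer bins, code values 0..63) of the six map signals,
#' concatenated in the order b1, b2, t1, t2, c1, c2: 384 counts in total.
#' Each histogram sums to `length(signal) - 48`. The features are invariant
#' under positive affine transforms of the signal.
#'
#' @inheritParams map_signals
#' @return Named integer vector of length 384 (names like `"b1_000"`).
#' @examples
#' fv <- frustum_features(sin(seq_len(200) / 5))
#' length(fv)
#' sum(fv[1:64])  # = 200 - 48
#' @export
frustum_features <- function(signal, sd_type = "sample") {
  maps <- map_signals(signal, sd_type)
  out <- unlist(lapply(maps, function(m) tabulate(m + 1L, nbins = 64L)))
  names(out) <- frustum_feature_names()
  out
}

#' Names of the 384 frustum features
#' @return Character vector like `"b1_000" ... "c2_063"`.
#' @export
frustum_feature_names <- function() {
  paste0(rep(c("b1", "b2", "t1", "t2", "c1", "c2"), each = 64L),
         "_", sprintf("%03d", 0:63))
}
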
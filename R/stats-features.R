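# 15 statistical moments, applied to the raw signal and to |signal|:
# mean, median, variance, Shannon entropy, log-energy entropy, maximum,
# minimum, standard deviation, range, SURE entropy, kurtosis, skewness,
# Higuchi fractal dimension, energy, root mean square.
# The entropies are the unnormalised wavelet-entropy forms (squared
# coefficients), the convention used for wavelet subband features.

#' Wavelet-style entropies
#'
#' * Shannon: `-sum(x^2 * log(x^2))`, with `0 * log(0) := 0`.
#' * Log-energy: `sum(log(x^2))`, with `log(0) := 0`.
#' * SURE: `n - #\{|x| <= eps\} + sum(min(x^2, eps^2))`.
#'
#' @param signal numeric vector.
#' @param sure_eps positive SURE threshold (default 3).
#' @return Named numeric vector `c(shannon, log_energy, sure)`.
#' @export
wavelet_entropies <- function(signal, sure_eps = 3) {
  stopifnot(is.numeric(signal), length(signal) >= 1, sure_eps > 0)
  x2 <- signal^2
  lx2 <- ifelse(x2 > 0, log(x2), 0)
  c(shannon = -sum(x2 * lx2),
    log_energy = sum(lx2),
    sure = length(signal) - sum(abs(signal) <= sure_eps) +
      sum(pmin(x2, sure_eps^2)))
}

#' Higuchi fractal dimension
#'
#' Curve-length complexity estimate: for each scale `k = 1..kmax` and offset
#' `m = 1..k`, the normalised length of the decimated sub-series is computed;
#' the dimension is the least-squares slope of `log L(k)` versus
#' `log(1 / k)`. A ramp gives ~1, white noise ~2. A constant signal returns
#' 1 by convention.
#'
#' @param signal numeric vector with `length(signal) > kmax`.
#' @param kmax largest scale, integer >= 2 (default 10).
#' @return Scalar fractal-dimension estimate.
#' @export
higuchi_fd <- function(signal, kmax = 10L) {
  n <- length(signal)
  stopifnot(kmax >= 2)
  if (n <= kmax) stop("signal must be longer than kmax")
  Lk <- numeric(kmax)
  for (k in seq_len(kmax)) {
    Lm <- numeric(k)
    for (m in seq_len(k)) {
      idx <- seq(m, n, by = k)
      nm <- length(idx) - 1L
      if (nm < 1L) { Lm[m] <- NA_real_; next }
      Lm[m] <- sum(abs(diff(signal[idx]))) * (n - 1) / (nm * k) / k
    }
    Lk[k] <- mean(Lm, na.rm = TRUE)
  }
  if (all(Lk == 0)) return(1)
  ok <- Lk > 0
  if (sum(ok) < 2) return(1)
  # least-squares slope of log L(k) on log(1/k)
  lx <- log(1 / seq_len(kmax)[ok])
  ly <- log(Lk[ok])
  sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
}

# Pearson (non-excess) kurtosis and population skewness
moment_stats <- function(x) {
  n <- length(x)
  m <- mean(x)
  c2 <- mean((x - m)^2)
  if (c2 == 0) return(c(kurtosis = 0, skewness = 0))
  c(kurtosis = mean((x - m)^4) / c2^2, skewness = mean((x - m)^3) / c2^1.5)
}

stat15 <- function(x, sure_eps, kmax) {
  ent <- wavelet_entropies(x, sure_eps)
  ms <- moment_stats(x)
  c(mean = mean(x), median = stats::median(x), variance = stats::var(x),
    shannon = unname(ent["shannon"]), log_energy = unname(ent["log_energy"]),
    maximum = max(x), minimum = min(x), sd = stats::sd(x),
    range = max(x) - min(x), sure = unname(ent["sure"]),
    kurtosis = unname(ms["kurtosis"]), skewness = unname(ms["skewness"]),
    higuchi = higuchi_fd(x, kmax), energy = sum(x^2),
    rms = sqrt(mean(x^2)))
}

#' Thirty statistical features
#'
#' The 15 moments in fixed order (mean, median, variance, Shannon entropy,
#' log-energy entropy, maximum, minimum, standard deviation, range, SURE
#' entropy, kurtosis, skewness, Higuchi fractal dimension, energy, RMS),
#' computed first on the signal, then on its absolute value.
#'
#' @param signal numeric vector, length >= 2 and longer than `kmax`.
#' @param sure_eps SURE entropy threshold (default 3).
#' @param kmax Higuchi scale bound (default 10).
#' @return Named numeric vector of length 30 (suffix `_raw` / `_abs`).
#' @examples
#' statistical_features(rnorm(100))[c("mean_raw", "rms_raw")]
#' @export
statistical_features <- function(signal, sure_eps = 3, kmax = 10L) {
  if (!is.numeric(signal) || length(signal) < 2 || anyNA(signal))
    stop("`signal` must be numeric of length >= 2 with no NA")
  out <- c(stat15(signal, sure_eps, kmax), stat15(abs(signal), sure_eps, kmax))
  names(out) <- statistical_feature_names()
  out
}

#' Names of the 30 statistical features
#' @return Character vector like `"mean_raw" ... "rms_abs"`.
#' @export
statistical_feature_names <- function() {
  base <- c("mean", "median", "variance", "shannon", "log_energy", "maximum",
            "minimum", "sd", "range", "sure", "kurtosis", "skewness",
            "higuchi", "energy", "rms")
  c(paste0(base, "_raw"), paste0(base, "_abs"))
}
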
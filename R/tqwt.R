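# Tunable Q-factor wavelet transform: radix-free frequency-domain filter bank.
# Each level splits the current low-pass band into a scaled low-pass part
# (length ~ alpha * N) and a high-pass part (length ~ beta * N) using
# Daubechies-type transition functions; the frame is Parseval-tight under the
# unitary DFT normalisation used here.

#' TQWT parameter set
#'
#' Builds a validated parameter object for the tunable Q-factor wavelet
#' transform. The quality factor `Q` controls the oscillatory resolution of
#' the wavelet, the redundancy `r` the frame oversampling, and `J` the number
#' of decomposition levels (giving `J + 1` subbands). The per-level scaling
#' factors are derived as `beta = 2 / (Q + 1)` and `alpha = 1 - beta / r`.
#'
#' @param Q quality factor, >= 1.
#' @param r redundancy (oversampling) factor, > 1.
#' @param J number of levels, integer >= 1.
#' @return An object of class `"tqwt_params"` with fields `Q`, `r`, `J`,
#'   `beta`, `alpha`.
#' @examples
#' p <- tqwt_params(1, 2, 6)
#' p$alpha
#' @export
tqwt_params <- function(Q, r, J) {
  stopifnot(is.numeric(Q), length(Q) == 1L, Q >= 1,
            is.numeric(r), length(r) == 1L, r > 1,
            is.numeric(J), length(J) == 1L, J >= 1, J == round(J))
  beta <- 2 / (Q + 1)
  alpha <- 1 - beta / r
  stopifnot(beta > 0, beta <= 1, alpha > 0, alpha < 1, alpha + beta > 1)
  structure(list(Q = Q, r = r, J = as.integer(J), beta = beta, alpha = alpha),
            class = "tqwt_params")
}

#' @export
print.tqwt_params <- function(x, ...) {
  cat(sprintf("TQWT parameters: Q = %g, r = %g, J = %d (alpha = %.4f, beta = %.4f)\n",
              x$Q, x$r, x$J, x$alpha, x$beta))
  invisible(x)
}

#' Maximum number of TQWT levels for a signal length
#'
#' The deepest level at which the high-pass subband still holds at least
#' eight samples: `floor(log(beta * N / 8) / log(1 / alpha))`.
#'
#' @param N signal length (after any padding to even length).
#' @param params a [tqwt_params()] object.
#' @return Integer, the maximal admissible `J`.
#' @export
tqwt_jmax <- function(N, params) {
  stopifnot(inherits(params, "tqwt_params"), N >= 8)
  as.integer(floor(log(params$beta * N / 8) / log(1 / params$alpha)))
}

# unitary DFT and inverse (real output)
udft <- function(x) stats::fft(x) / sqrt(length(x))
udft_inv <- function(X) Re(stats::fft(X, inverse = TRUE)) / sqrt(length(X))

# Daubechies frequency-response transition values on a T-point grid
trans_fun <- function(T) {
  if (T <= 0) return(numeric(0))
  v <- (1:T) * pi / (T + 1)
  (1 + cos(v)) * sqrt(2 - cos(v)) / 2
}

# one analysis step: X is the unitary DFT (even length N); returns the DFTs
# of the low-pass (length N0) and high-pass (length N1) subbands
tqwt_afb <- function(X, N0, N1) {
  N <- length(X)
  P <- (N - N1) / 2L            # low-pass pass-band bins
  T <- (N0 + N1 - N) / 2L - 1L  # transition bins
  S <- (N - N0) / 2L            # low-pass stop bins (= high-pass pass-band)
  if (T < 0 || P < 0 || S < 0 || N0 < 4 || N1 < 4)
    stop("signal too short for this TQWT parameterisation at the current level")
  th <- trans_fun(T)
  V0 <- complex(N0)
  V1 <- complex(N1)
  V0[1L] <- X[1L]
  if (P > 0) V0[2:(P + 1)] <- X[2:(P + 1)]
  if (T > 0) {
    tb <- X[(P + 2):(P + T + 1)]
    V0[(P + 2):(P + T + 1)] <- tb * th
    V1[2:(T + 1)] <- tb * rev(th)
  }
  V0[N0 / 2 + 1] <- 0
  if (S > 0) V1[(T + 2):(T + S + 1)] <- X[(P + T + 2):(P + T + S + 1)]
  V1[N1 / 2 + 1] <- X[N / 2 + 1]
  V0[(N0 / 2 + 2):N0] <- Conj(V0[(N0 / 2):2])
  V1[(N1 / 2 + 2):N1] <- Conj(V1[(N1 / 2):2])
  list(lo = V0, hi = V1)
}

# one synthesis step: inverse of tqwt_afb
tqwt_sfb <- function(V0, V1, N) {
  N0 <- length(V0)
  N1 <- length(V1)
  P <- (N - N1) / 2L
  T <- (N0 + N1 - N) / 2L - 1L
  S <- (N - N0) / 2L
  th <- trans_fun(T)
  X <- complex(N)
  X[1L] <- V0[1L]
  if (P > 0) X[2:(P + 1)] <- V0[2:(P + 1)]
  if (T > 0)
    X[(P + 2):(P + T + 1)] <- V0[(P + 2):(P + T + 1)] * th +
      V1[2:(T + 1)] * rev(th)
  if (S > 0) X[(P + T + 2):(P + T + S + 1)] <- V1[(T + 2):(T + S + 1)]
  X[N / 2 + 1] <- V1[N1 / 2 + 1]
  X[(N / 2 + 2):N] <- Conj(X[(N / 2):2])
  X
}

# subband lengths are derived from the original length at every level so that
# analysis and synthesis agree on the rounding
tqwt_lengths <- function(N, params, j) {
  list(N0 = 2 * round(params$alpha^j * N / 2),
       N1 = 2 * round(params$beta * params$alpha^(j - 1) * N / 2))
}

#' TQWT analysis
#'
#' Decomposes a real signal into `J + 1` subbands (levels `1..J` hold the
#' high-pass details from highest to lowest frequency; band `J + 1` is the
#' final low-pass). Odd-length inputs are zero-padded by one sample before
#' analysis; the pad is recorded and removed again by [tqwt_reconstruct()].
#'
#' @param signal numeric vector, length >= 8.
#' @param params a [tqwt_params()] object; `params$J` must not exceed
#'   [tqwt_jmax()] for the (padded) signal length.
#' @return An object of class `"tqwt_subbands"`: a list with `params`,
#'   `bands` (list of `J + 1` numeric vectors), `source_length`, `padded`.
#' @examples
#' x <- sin(2 * pi * 7 * seq(0, 1, length.out = 512))
#' sb <- tqwt_decompose(x, tqwt_params(1, 2, 6))
#' length(sb$bands)
#' @export
tqwt_decompose <- function(signal, params) {
  stopifnot(inherits(params, "tqwt_params"))
  if (!is.numeric(signal) || length(signal) < 8 || anyNA(signal))
    stop("`signal` must be a numeric vector of length >= 8 with no NA")
  source_length <- length(signal)
  padded <- source_length %% 2L == 1L
  if (padded) signal <- c(signal, 0)
  N <- length(signal)
  jmax <- tqwt_jmax(N, params)
  if (params$J > jmax)
    stop(sprintf("J = %d exceeds J_max = %d for signal length %d", params$J, jmax, N))
  X <- udft(signal)
  bands <- vector("list", params$J + 1L)
  for (j in seq_len(params$J)) {
    len <- tqwt_lengths(N, params, j)
    fb <- tqwt_afb(X, len$N0, len$N1)
    bands[[j]] <- udft_inv(fb$hi)
    X <- fb$lo
  }
  bands[[params$J + 1L]] <- udft_inv(X)
  structure(list(params = params, bands = bands,
                 source_length = source_length, padded = padded),
            class = "tqwt_subbands")
}

#' @export
print.tqwt_subbands <- function(x, ...) {
  cat(sprintf("TQWT subband set: %d bands (Q = %g, r = %g, J = %d), source length %d\n",
              length(x$bands), x$params$Q, x$params$r, x$params$J, x$source_length))
  invisible(x)
}

#' TQWT synthesis
#'
#' Perfect-reconstruction inverse of [tqwt_decompose()].
#'
#' @param sb a `"tqwt_subbands"` object.
#' @return Numeric vector of length `sb$source_length`.
#' @export
tqwt_reconstruct <- function(sb) {
  stopifnot(inherits(sb, "tqwt_subbands"))
  params <- sb$params
  J <- params$J
  if (length(sb$bands) != J + 1L) stop("band count does not match params$J + 1")
  N <- sb$source_length + as.integer(sb$padded)
  for (j in seq_len(J)) {
    len <- tqwt_lengths(N, params, j)
    if (length(sb$bands[[j]]) != len$N1)
      stop(sprintf("band %d has length %d, expected %d", j, length(sb$bands[[j]]), len$N1))
  }
  X <- udft(sb$bands[[J + 1L]])
  for (j in rev(seq_len(J))) {
    Nprev <- if (j == 1L) N else tqwt_lengths(N, params, j - 1L)$N0
    X <- tqwt_sfb(X, udft(sb$bands[[j]]), Nprev)
  }
  x <- udft_inv(X)
  if (sb$padded) x <- x[-length(x)]
  x
}

#' Default multi-parameter TQWT configuration
#'
#' The four parameterizations used by the Frustum154 feature generator:
#' (Q, r, J) = (1, 2, 6), (2, 4, 24), (3, 6, 46), (4, 8, 73), which produce
#' 7 + 25 + 47 + 74 = 153 subbands.
#'
#' @return A list of four [tqwt_params()] objects.
#' @export
default_tqwt_params <- function() {
  list(tqwt_params(1, 2, 6), tqwt_params(2, 4, 24),
       tqwt_params(3, 6, 46), tqwt_params(4, 8, 73))
}

#' Multi-parameter TQWT decomposition
#'
#' Runs [tqwt_decompose()] once per parameter set and concatenates the
#' resulting subbands in order (within each set: details level 1..J, then the
#' final low-pass). With the default parameters and a signal long enough for
#' 73 levels at (Q = 4, r = 8) this yields 153 subbands.
#'
#' @param signal numeric vector.
#' @param params_list list of [tqwt_params()] objects.
#' @return A list with `bands` (list of numeric vectors) and `provenance`
#'   (data.frame with `set`, `Q`, `r`, `level` per band).
#' @export
multi_tqwt <- function(signal, params_list = default_tqwt_params()) {
  stopifnot(is.list(params_list), length(params_list) >= 1)
  bands <- list()
  prov <- list()
  for (s in seq_along(params_list)) {
    p <- params_list[[s]]
    sb <- tqwt_decompose(signal, p)
    bands <- c(bands, sb$bands)
    prov[[s]] <- data.frame(set = s, Q = p$Q, r = p$r, level = seq_len(p$J + 1L))
  }
  list(bands = bands, provenance = do.call(rbind, prov))
}
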
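# Shared fixtures. Heavier objects are computed lazily and cached for the
# whole test run.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, .fixture_env, inherits = FALSE))
    assign(name, expr, .fixture_env)
  get(name, .fixture_env)
}

# naive per-block reference for the frustum pattern, written directly from
# the definition (independent of the vectorized map_signals path)
naive_map_signals <- function(x, d) {
  n <- length(x) - 48L
  codes <- matrix(0L, 6L, n)
  for (i in seq_len(n)) {
    m <- matrix(x[i:(i + 48L)], nrow = 7, byrow = TRUE)
    v <- as.vector(t(m))
    bidx <- c(2L, 6L, 28L, 48L, 44L, 22L)
    tidx <- c(10L, 12L, 27L, 40L, 38L, 23L)
    pairs <- list(cbind(bidx, c(bidx[-1], bidx[1])),
                  cbind(tidx, c(tidx[-1], tidx[1])),
                  cbind(bidx, tidx))
    k <- 1L
    for (pr in pairs) {
      up <- lo <- 0L
      for (j in 1:6) {
        df <- v[pr[j, 1]] - v[pr[j, 2]]
        if (df > d) up <- up + 2L^(j - 1L)
        if (df < -d) lo <- lo + 2L^(j - 1L)
      }
      codes[k, i] <- up
      codes[k + 1L, i] <- lo
      k <- k + 2L
    }
  }
  codes
}

# a small well-separated synthetic dataset whose trials are long enough for
# the full four-parameter TQWT (concatenated length 5000)
small_synth <- function() cached("small_synth",
  synth_dataset(n_per_class = 8, duration_s = 5, fs = 500, seed = 11))

small_features <- function() cached("small_features",
  extract_dataset_features(small_synth()))

small_fit <- function() cached("small_fit",
  frustum154(small_synth(), folds = 4, seed = 11, inca_stride = 32,
             nca_iterations = 60))

# MAT-file fixture directory written by scipy (independent writer); one
# trial per class, 100 samples per channel
mat_fixture_dir <- function() cached("mat_fixture_dir", {
  dir <- file.path(tempdir(), "mat_fixture")
  dir.create(dir, showWarnings = FALSE)
  script <- sprintf("
import numpy as np, scipy.io as sio
np.random.seed(42)
d = {}
for p in ['cyl', 'hook', 'lat', 'palm', 'spher', 'tip']:
    d[p + '_ch1'] = np.random.randn(1, 100)
    d[p + '_ch2'] = np.random.randn(1, 100)
sio.savemat(r'%s', d, do_compression=True)
sio.savemat(r'%s', d, do_compression=False)
", file.path(dir, "subject_a.mat"), file.path(dir, "subject_b.mat"))
  status <- system2("python", "-", input = script, stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("python/scipy unavailable to write the MAT fixture")
  dir
})
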
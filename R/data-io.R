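# Datasets of labeled two-channel sEMG trials. The six grasp classes follow
# the canonical order C, H, L, P, S, T used throughout reports and
# confusion matrices.

#' The six grasp classes
#'
#' Canonical ordering: C (cylindrical), H (hook), L (lateral), P (palmar),
#' S (spherical), T (tip).
#'
#' @return Named character vector of the six class codes.
#' @export
grasp_classes <- function() {
  c(cylindrical = "C", hook = "H", lateral = "L",
    palmar = "P", spherical = "S", tip = "T")
}

grasp_factor <- function(labels) {
  f <- factor(as.character(labels), levels = unname(grasp_classes()))
  if (anyNA(f)) stop("labels must be grasp class codes C, H, L, P, S or T")
  f
}

#' One labeled sEMG trial
#'
#' @param ch1,ch2 numeric channel recordings of equal nonzero length.
#' @param fs sampling rate in Hz (default 500).
#' @param label grasp class code (see [grasp_classes()]).
#' @param meta optional list of tags (subject, session, ...).
#' @return An object of class `"signal_record"`.
#' @export
signal_record <- function(ch1, ch2, fs = 500, label, meta = list()) {
  if (!is.numeric(ch1) || !is.numeric(ch2) || length(ch1) == 0L)
    stop("channels must be nonempty numeric vectors")
  if (length(ch1) != length(ch2))
    stop("ch1 and ch2 must have the same length")
  stopifnot(fs > 0)
  label <- as.character(grasp_factor(label))
  structure(list(ch1 = as.numeric(ch1), ch2 = as.numeric(ch2),
                 fs = fs, label = label, meta = meta),
            class = "signal_record")
}

#' Concatenate the two sEMG channels
#'
#' The model input is the channel concatenation: first all of channel 1,
#' then all of channel 2.
#'
#' @param ch1,ch2 numeric vectors of equal nonzero length.
#' @return Numeric vector of length `length(ch1) + length(ch2)`.
#' @examples
#' concat_channels(c(1, 2), c(3, 4))
#' @export
concat_channels <- function(ch1, ch2) {
  if (!is.numeric(ch1) || !is.numeric(ch2) || length(ch1) == 0L)
    stop("channels must be nonempty numeric vectors")
  if (length(ch1) != length(ch2))
    stop("ch1 and ch2 must have the same length")
  c(as.numeric(ch1), as.numeric(ch2))
}

record_signal <- function(record) concat_channels(record$ch1, record$ch2)

#' A labeled collection of sEMG trials
#'
#' @param records list of [signal_record()] objects sharing one sampling
#'   rate.
#' @param name dataset tag (e.g. "DB1", "DB2", "DB3", "synthetic").
#' @return An object of class `"grasp_dataset"`.
#' @export
grasp_dataset <- function(records, name = "dataset") {
  if (!is.list(records) || length(records) == 0L)
    stop("`records` must be a nonempty list of signal records")
  ok <- vapply(records, inherits, logical(1), "signal_record")
  if (!all(ok)) stop("all records must be signal_record objects")
  fs <- unique(vapply(records, function(r) r$fs, numeric(1)))
  if (length(fs) != 1L) stop("all records must share one sampling rate")
  structure(list(records = records, name = name, fs = fs),
            class = "grasp_dataset")
}

#' @export
print.grasp_dataset <- function(x, ...) {
  tab <- table(dataset_labels(x))
  cat(sprintf("Grasp dataset '%s': %d records at %g Hz\n",
              x$name, length(x$records), x$fs))
  print(tab)
  invisible(x)
}

#' @export
length.grasp_dataset <- function(x) length(x$records)

#' Labels of a dataset, as a factor in canonical class order
#' @param dataset a [grasp_dataset()].
#' @return Factor of length `length(dataset)`.
#' @export
dataset_labels <- function(dataset) {
  stopifnot(inherits(dataset, "grasp_dataset"))
  grasp_factor(vapply(dataset$records, function(r) r$label, character(1)))
}

#' Merge two datasets into a fused one
#'
#' Concatenates the records of both inputs (first dataset first). Both must
#' be nonempty, share the sampling rate, and cover the same class set; this
#' mirrors how the fused benchmark DB3 is built from DB1 and DB2.
#'
#' @param db1,db2 [grasp_dataset()] objects.
#' @param name name of the merged dataset (default "DB3").
#' @return A [grasp_dataset()] with `length(db1) + length(db2)` records.
#' @export
build_db3 <- function(db1, db2, name = "DB3") {
  stopifnot(inherits(db1, "grasp_dataset"), inherits(db2, "grasp_dataset"))
  if (length(db1) == 0L || length(db2) == 0L) stop("empty dataset rejected")
  if (db1$fs != db2$fs) stop("sampling rates differ")
  c1 <- sort(unique(as.character(dataset_labels(db1))))
  c2 <- sort(unique(as.character(dataset_labels(db2))))
  if (!identical(c1, c2)) stop("class sets differ between the two datasets")
  grasp_dataset(c(db1$records, db2$records), name = name)
}

# run code under a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# AR(4) coefficients from two complex pole pairs (radii rho, angles omega)
ar4_coefs <- function(omega1, omega2, rho1 = 0.92, rho2 = 0.85) {
  p1 <- c(1, -2 * rho1 * cos(omega1), rho1^2)
  p2 <- c(1, -2 * rho2 * cos(omega2), rho2^2)
  phi <- stats::convolve(p1, rev(p2), type = "open")  # polynomial product
  -phi[-1]  # x_t = sum(ar * x_{t-1..t-4}) + e_t
}

#' Seeded synthetic sEMG dataset
#'
#' Emulates labeled two-channel band-limited stochastic signals: each class
#' is an order-4 autoregressive process (two complex pole pairs whose angles
#' are spread across classes by `separation`), driven by unit-variance
#' Gaussian innovations and amplitude-modulated by a class-weighted Hann
#' envelope — the common "amplitude-modulated colored noise" model of sEMG.
#' Fully reproducible from `seed`; the caller's RNG state is untouched.
#'
#' @param n_per_class trials per class, >= 1 (default 30).
#' @param duration_s trial duration per channel in seconds (default 6).
#' @param fs sampling rate in Hz (default 500).
#' @param seed integer seed.
#' @param separation nonnegative spread of the class pole angles (default 1);
#'   0 makes all classes spectrally identical.
#' @return A [grasp_dataset()] with `6 * n_per_class` records, named
#'   "synthetic".
#' @examples
#' ds <- synth_dataset(n_per_class = 2, duration_s = 0.5, fs = 500, seed = 1)
#' length(ds)
#' @export
synth_dataset <- function(n_per_class = 30, duration_s = 6, fs = 500,
                          seed = 1, separation = 1) {
  stopifnot(n_per_class >= 1, n_per_class == round(n_per_class),
            duration_s > 0, fs > 0, separation >= 0)
  n <- round(duration_s * fs)
  if (2 * n < 49) stop("trials too short: need duration_s * fs >= 24.5")
  classes <- unname(grasp_classes())
  # class pole angles inside the typical sEMG band, spread by `separation`
  base <- pi * 0.14
  step <- pi * 0.045 * separation
  env <- 0.35 + 0.65 * (0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1)))  # Hann
  records <- with_seed(seed, {
    recs <- vector("list", 6L * n_per_class)
    idx <- 1L
    for (k in seq_along(classes)) {
      w1 <- min(base + step * (k - 1), pi * 0.93)
      w2 <- min(w1 + pi * 0.11, pi * 0.97)
      ar <- ar4_coefs(w1, w2)
      amp <- 1 + 0.15 * (k - 1)  # class-specific envelope weight
      for (t in seq_len(n_per_class)) {
        ch <- replicate(2, {
          x <- stats::arima.sim(list(ar = ar), n = n, n.start = 200)
          as.numeric(x) * env * amp
        }, simplify = FALSE)
        recs[[idx]] <- signal_record(ch[[1]], ch[[2]], fs = fs,
                                     label = classes[k],
                                     meta = list(trial = t, class = classes[k]))
        idx <- idx + 1L
      }
    }
    recs
  })
  grasp_dataset(records, name = "synthetic")
}

#' Write a dataset to a directory of CSV files
#'
#' One `signals.csv` with one row per trial and channel: `label`, `channel`,
#' then the samples, plus a small `meta.csv`.
#'
#' @param dataset a [grasp_dataset()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_dataset_csv <- function(dataset, dir) {
  stopifnot(inherits(dataset, "grasp_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(seq_along(dataset$records), function(i) {
    r <- dataset$records[[i]]
    rbind(data.frame(trial = i, label = r$label, channel = 1L,
                     t(r$ch1), check.names = FALSE),
          data.frame(trial = i, label = r$label, channel = 2L,
                     t(r$ch2), check.names = FALSE))
  })
  sig_path <- file.path(dir, "signals.csv")
  utils::write.csv(do.call(rbind, rows), sig_path, row.names = FALSE)
  meta_path <- file.path(dir, "meta.csv")
  utils::write.csv(data.frame(name = dataset$name, fs = dataset$fs,
                              n_records = length(dataset)),
                   meta_path, row.names = FALSE)
  invisible(c(sig_path, meta_path))
}

#' Read a dataset from the CSV layout of [write_dataset_csv()]
#'
#' @param dir directory containing `signals.csv` and `meta.csv`.
#' @return A [grasp_dataset()].
#' @export
read_dataset_csv <- function(dir) {
  sig <- utils::read.csv(file.path(dir, "signals.csv"), check.names = FALSE)
  meta <- utils::read.csv(file.path(dir, "meta.csv"))
  recs <- lapply(unique(sig$trial), function(tr) {
    sub <- sig[sig$trial == tr, , drop = FALSE]
    samp <- as.matrix(sub[, -(1:3), drop = FALSE])
    signal_record(as.numeric(samp[sub$channel == 1L, ]),
                  as.numeric(samp[sub$channel == 2L, ]),
                  fs = meta$fs[1], label = sub$label[1])
  })
  grasp_dataset(recs, name = as.character(meta$name[1]))
}
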
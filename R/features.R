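# Per-source feature vectors: 384 frustum-pattern counts + 30 statistical
# moments = 414 features, computed for the raw concatenated signal
# (source 0) and every TQWT subband (sources 1..153 with the default
# multi-parameter configuration).

#' Names of the 414 per-source features
#' @return Character vector: frustum names then statistical names.
#' @export
feature_names414 <- function() c(frustum_feature_names(), statistical_feature_names())

# 414 features for one source signal; bands shorter than 49 samples are
# zero-padded for the frustum part only
source_features <- function(x, sure_eps = 3, kmax = 10L, sd_type = "sample") {
  xf <- x
  if (length(xf) < 49) {
    warning(sprintf("source has %d samples (< 49); frustum part computed on a zero-padded copy",
                    length(xf)))
    xf <- c(xf, numeric(49 - length(xf)))
  }
  c(frustum_features(xf, sd_type), statistical_features(x, sure_eps, kmax))
}

#' All 154 feature vectors for one trial
#'
#' Source 0 is the concatenated raw signal; sources 1..153 are the
#' [multi_tqwt()] subbands in order. Each source yields 414 features
#' (frustum pattern then statistical moments).
#'
#' @param record a [signal_record()] or a plain numeric signal.
#' @param params_list TQWT parameter sets (default [default_tqwt_params()]).
#' @param sure_eps,kmax,sd_type passed to the feature extractors.
#' @return A numeric matrix with one row per source (rownames `"0"..."153"`)
#'   and 414 named columns; attribute `"provenance"` carries the TQWT
#'   set/level of each subband source.
#' @export
extract_all_feature_vectors <- function(record,
                                        params_list = default_tqwt_params(),
                                        sure_eps = 3, kmax = 10L,
                                        sd_type = "sample") {
  x <- if (inherits(record, "signal_record")) record_signal(record)
       else as.numeric(record)
  if (length(x) < 49) stop("concatenated signal must have at least 49 samples")
  mt <- multi_tqwt(x, params_list)
  sources <- c(list(x), mt$bands)
  out <- t(vapply(sources, source_features, numeric(414),
                  sure_eps = sure_eps, kmax = kmax, sd_type = sd_type))
  dimnames(out) <- list(source = as.character(seq_along(sources) - 1L),
                        feature = feature_names414())
  attr(out, "provenance") <- rbind(
    data.frame(set = 0L, Q = NA_real_, r = NA_real_, level = 0L),
    mt$provenance)
  out
}

#' Per-source feature sets for a whole dataset
#'
#' Runs [extract_all_feature_vectors()] on every record and regroups the
#' result by source: a list of `n_sources` matrices, each
#' `n_records x 414`.
#'
#' @param dataset a [grasp_dataset()].
#' @inheritParams extract_all_feature_vectors
#' @param verbose print progress every 25 records.
#' @return List of class `"feature_sets"`: `sets` (list of matrices),
#'   `labels` (factor), `provenance`.
#' @export
extract_dataset_features <- function(dataset,
                                     params_list = default_tqwt_params(),
                                     sure_eps = 3, kmax = 10L,
                                     sd_type = "sample", verbose = FALSE) {
  stopifnot(inherits(dataset, "grasp_dataset"))
  n <- length(dataset)
  per_rec <- vector("list", n)
  for (i in seq_len(n)) {
    per_rec[[i]] <- extract_all_feature_vectors(dataset$records[[i]],
                                                params_list, sure_eps, kmax,
                                                sd_type)
    if (verbose && i %% 25L == 0L) message(sprintf("  features: %d/%d records", i, n))
  }
  n_src <- nrow(per_rec[[1]])
  sets <- lapply(seq_len(n_src), function(s)
    do.call(rbind, lapply(per_rec, function(m) m[s, ])))
  structure(list(sets = sets, labels = dataset_labels(dataset),
                 provenance = attr(per_rec[[1]], "provenance")),
            class = "feature_sets")
}

#' Column-wise min-max normalization
#'
#' Scales every column to `[0, 1]` by its own minimum and maximum over the
#' observations; constant columns map to 0.
#'
#' @param m numeric matrix with at least 2 rows.
#' @return Matrix of the same shape with values in `[0, 1]`.
#' @export
minmax_normalize <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("min-max normalization needs at least 2 observations")
  lo <- apply(m, 2, min)
  hi <- apply(m, 2, max)
  span <- hi - lo
  span[span == 0] <- 1  # constant columns -> 0 after centring
  out <- sweep(sweep(m, 2, lo), 2, span, `/`)
  out
}

#' Write a feature matrix to CSV
#'
#' One row per observation, stable header names, with the label as the
#' first column when given.
#'
#' @param m feature matrix with column names.
#' @param path output CSV path.
#' @param labels optional label vector.
#' @export
write_features_csv <- function(m, path, labels = NULL) {
  df <- as.data.frame(m, check.names = FALSE)
  if (!is.null(labels)) df <- cbind(label = as.character(labels), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
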
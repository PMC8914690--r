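# Loss-driven subband selection: every one of the 154 per-source feature
# vectors is scored by cross-validated misclassification under both shallow
# classifiers; the family with the lower mean loss is kept (greedy choice)
# and the top 20 sources are merged into the 414 * 20 = 8280-column matrix.

#' Cross-validated loss of every feature source
#'
#' For each source, the 414 features are min-max normalized and scored by
#' stratified k-fold misclassification under 1-NN (L1) and the cubic SVM.
#' The chosen family is the one with the lower mean loss across sources.
#'
#' @param feature_sets a `"feature_sets"` object from
#'   [extract_dataset_features()], or a plain list of `n x 414` matrices.
#' @param labels labels (required when `feature_sets` is a plain list).
#' @param folds CV folds (default 10).
#' @param seed fold-assignment seed (default 0).
#' @param verbose print progress every 25 sources.
#' @return A data.frame of class `"loss_table"` with columns `source_id`,
#'   `loss_knn`, `loss_svm`, `loss` (the chosen family's loss); attribute
#'   `"chosen_classifier"` is `"knn"` or `"svm"`.
#' @export
vector_losses <- function(feature_sets, labels = NULL, folds = 10L, seed = 0L,
                          verbose = FALSE) {
  if (inherits(feature_sets, "feature_sets")) {
    labels <- feature_sets$labels
    sets <- feature_sets$sets
  } else sets <- feature_sets
  if (is.null(labels)) stop("labels are required")
  y <- as.factor(labels)
  if (nlevels(droplevels(y)) < 2) stop("labels must cover at least 2 classes")
  if (nrow(sets[[1]]) < folds) stop("fewer observations than folds")
  kspec <- classifier_spec("knn")
  sspec <- classifier_spec("svm")
  n_src <- length(sets)
  loss_knn <- numeric(n_src)
  loss_svm <- numeric(n_src)
  for (s in seq_len(n_src)) {
    Xn <- minmax_normalize(sets[[s]])
    loss_knn[s] <- crossval_loss(Xn, y, kspec, folds, seed)
    loss_svm[s] <- crossval_loss(Xn, y, sspec, folds, seed)
    if (verbose && s %% 25L == 0L) message(sprintf("  losses: %d/%d sources", s, n_src))
  }
  chosen <- if (mean(loss_knn) <= mean(loss_svm)) "knn" else "svm"
  out <- data.frame(source_id = seq_len(n_src) - 1L,
                    loss_knn = loss_knn, loss_svm = loss_svm,
                    loss = if (chosen == "knn") loss_knn else loss_svm)
  attr(out, "chosen_classifier") <- chosen
  class(out) <- c("loss_table", "data.frame")
  out
}

#' Merge the best feature sources
#'
#' Ranks sources by the chosen classifier's loss (ties broken by the
#' smaller source id), keeps the best `top`, and concatenates their
#' normalized 414-column blocks in rank order.
#'
#' @param feature_sets as in [vector_losses()].
#' @param loss_table a `"loss_table"` from [vector_losses()].
#' @param top number of sources to keep (default 20).
#' @return A list of class `"merged_features"`: `features`
#'   (`n x 414 * top` matrix, min-max normalized), `selected_sources`
#'   (ids in rank order), `provenance` (data.frame mapping every column to
#'   its source and within-source feature).
#' @export
select_and_merge <- function(feature_sets, loss_table, top = 20L) {
  if (inherits(feature_sets, "feature_sets")) sets <- feature_sets$sets
  else sets <- feature_sets
  stopifnot(inherits(loss_table, "loss_table"))
  if (top < 1) stop("`top` must be at least 1")
  if (top > nrow(loss_table)) stop("`top` exceeds the number of sources")
  ord <- order(loss_table$loss, loss_table$source_id)  # ties -> smaller id
  sel <- loss_table$source_id[ord[seq_len(top)]]
  blocks <- lapply(sel, function(id) minmax_normalize(sets[[id + 1L]]))
  merged <- do.call(cbind, blocks)
  prov <- data.frame(column = seq_len(ncol(merged)),
                     source_id = rep(sel, each = 414L),
                     within_index = rep(seq_len(414L), times = top),
                     feature = rep(feature_names414(), times = top))
  colnames(merged) <- paste0("s", prov$source_id, ".", prov$feature)
  structure(list(features = merged, selected_sources = sel, provenance = prov),
            class = "merged_features")
}
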
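# End-to-end Frustum154 model: channel concatenation -> multi-parameter
# TQWT -> 154 x 414 features -> per-source normalization -> loss-driven
# subband ranking -> top-k merge -> INCA -> final cross-validated shallow
# classifier, packaged as a classed model object.

#' Fit the Frustum154 grasp-classification model
#'
#' Runs the full learning network on a labeled dataset:
#' 1. each trial's two channels are concatenated;
#' 2. the multi-parameter TQWT produces 153 subbands, so together with the
#'    raw signal there are 154 feature sources;
#' 3. every source yields 414 features (384 frustum-pattern counts + 30
#'    statistical moments), min-max normalized per source;
#' 4. every source is scored by stratified k-fold misclassification under
#'    1-NN (L1) and cubic SVM; the family with the lower mean loss is kept
#'    (`classifier = "auto"`) and the best `top_k` sources are merged
#'    (`414 * top_k` columns);
#' 5. INCA ranks the merged features by NCA weight and keeps the
#'    loss-minimizing prefix within `inca_range`;
#' 6. the selected features are classified with the chosen family under
#'    k-fold cross-validation, giving the final evaluation report.
#'
#' The fit is a pure function of the dataset, the configuration and `seed`.
#'
#' @param dataset a [grasp_dataset()] with at least `folds` trials per
#'   class, or a `"feature_sets"` object from [extract_dataset_features()]
#'   (useful to re-run selection without re-extracting features).
#' @param top_k number of feature sources to merge (default 20).
#' @param folds cross-validation folds (default 10).
#' @param seed integer seed driving fold assignment and NCA initialization.
#' @param classifier `"auto"` (greedy choice by mean source loss), `"knn"`
#'   or `"svm"`.
#' @param inca_range INCA size sweep bounds (default `c(100, 512)`).
#' @param inca_stride sweep step (default 1).
#' @param params_list TQWT parameter sets (default [default_tqwt_params()]).
#' @param nca_iterations NCA gradient-ascent budget.
#' @param verbose print stage progress.
#' @return An object of class `"frustum154"`; see [predict.frustum154()],
#'   `print`, `summary`, `plot`, `coef`.
#' @examples
#' \donttest{
#' ds <- synth_dataset(n_per_class = 12, duration_s = 2.2, seed = 1)
#' fit <- frustum154(ds, folds = 4, inca_stride = 64, seed = 1)
#' fit$report$accuracy
#' }
#' @export
frustum154 <- function(dataset, top_k = 20L, folds = 10L, seed = 0L,
                       classifier = c("auto", "knn", "svm"),
                       inca_range = c(100L, 512L), inca_stride = 1L,
                       params_list = default_tqwt_params(),
                       nca_iterations = 100L, verbose = FALSE) {
  classifier <- match.arg(classifier)
  cl <- match.call()
  say <- function(...) if (verbose) message(sprintf(...))
  if (inherits(dataset, "grasp_dataset")) {
    say("extracting %d x 414 features for %d records ...",
        length(params_list_total_bands(params_list)) + 1L, length(dataset))
    fs <- extract_dataset_features(dataset, params_list, verbose = verbose)
  } else if (inherits(dataset, "feature_sets")) {
    fs <- dataset
  } else stop("`dataset` must be a grasp_dataset or feature_sets object")
  y <- fs$labels
  say("scoring %d sources with %d-fold CV ...", length(fs$sets), folds)
  lt <- vector_losses(fs, folds = folds, seed = seed, verbose = verbose)
  family <- if (classifier == "auto") attr(lt, "chosen_classifier") else classifier
  say("chosen classifier: %s; merging top %d sources ...", family, top_k)
  merged <- select_and_merge(fs, lt, top = top_k)
  say("INCA sweep over [%d, %d] (stride %d) ...",
      inca_range[1], inca_range[2], inca_stride)
  inca <- inca_select(merged$features, y, size_range = inca_range,
                      classifier = family, folds = folds, seed = seed,
                      stride = inca_stride, nca_iterations = nca_iterations)
  Xsel <- merged$features[, inca$selected_indices, drop = FALSE]
  spec <- classifier_spec(family)
  say("final %d-fold CV on %d selected features ...", folds, ncol(Xsel))
  pred <- crossval_predict(Xsel, y, spec, folds, seed)
  report <- evaluation_report(y, pred)
  # training-set normalization bounds per selected source, for predict()
  sel_stats <- lapply(merged$selected_sources, function(id) {
    m <- fs$sets[[id + 1L]]
    list(lo = apply(m, 2, min), hi = apply(m, 2, max))
  })
  final <- train_classifier(Xsel, y, spec, seed)
  structure(list(call = cl,
                 config = list(top_k = top_k, folds = folds, seed = seed,
                               classifier = classifier,
                               inca_range = inca_range,
                               inca_stride = inca_stride,
                               params_list = params_list),
                 chosen_classifier = family,
                 loss_table = lt,
                 selected_sources = merged$selected_sources,
                 provenance = merged$provenance,
                 inca = inca,
                 cv_predictions = pred,
                 report = report,
                 labels = y,
                 source_stats = sel_stats,
                 final_model = final),
            class = "frustum154")
}

params_list_total_bands <- function(params_list)
  unlist(lapply(params_list, function(p) seq_len(p$J + 1L)))

#' @export
print.frustum154 <- function(x, ...) {
  cat("Frustum154 grasp-classification model\n")
  cat(sprintf("  records: %d   classifier: %s (%s)\n",
              length(x$labels), x$chosen_classifier,
              if (x$config$classifier == "auto") "auto-selected" else "fixed"))
  cat(sprintf("  merged sources: %s ...\n",
              paste(utils::head(x$selected_sources, 8), collapse = ", ")))
  cat(sprintf("  INCA: %d of %d merged features selected\n",
              x$inca$selected_size, nrow(x$provenance)))
  cat(sprintf("  cross-validated accuracy: %.2f%%\n", x$report$accuracy))
  invisible(x)
}

#' @export
summary.frustum154 <- function(object, ...) {
  cat("Frustum154 model summary\n")
  cat(sprintf("Chosen classifier: %s; mean source loss: knn %.4f, svm %.4f\n",
              object$chosen_classifier, mean(object$loss_table$loss_knn),
              mean(object$loss_table$loss_svm)))
  cat(sprintf("Selected sources (rank order): %s\n",
              paste(object$selected_sources, collapse = ", ")))
  cat(sprintf("INCA selected size: %d (loss %.4f)\n",
              object$inca$selected_size, object$inca$selected_loss))
  print(object$report)
  invisible(object)
}

#' @export
coef.frustum154 <- function(object, ...) {
  stats::setNames(object$inca$weights,
                  paste0("s", object$provenance$source_id, ".",
                         object$provenance$feature))
}

#' Plot the two selection stages of a Frustum154 fit
#'
#' Left: per-source misclassification of the chosen loss generator (the
#' merged sources highlighted). Right: the INCA loss curve over subset
#' sizes, with the selected size marked.
#'
#' @param x a `"frustum154"` object.
#' @param ... ignored.
#' @export
plot.frustum154 <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  lt <- x$loss_table
  graphics::plot(lt$source_id, lt$loss, pch = 16, cex = 0.5,
                 xlab = "feature source (0 = raw signal)",
                 ylab = "misclassification rate",
                 main = sprintf("source losses (%s)", x$chosen_classifier))
  sel <- lt$source_id %in% x$selected_sources
  graphics::points(lt$source_id[sel], lt$loss[sel], pch = 16, col = 2)
  graphics::plot(x$inca$sizes, x$inca$loss_curve, type = "b", pch = 16,
                 cex = 0.6, xlab = "number of features",
                 ylab = "misclassification rate", main = "INCA sweep")
  graphics::abline(v = x$inca$selected_size, lty = 2, col = 2)
  invisible(x)
}

#' Predict grasp classes for new trials
#'
#' Applies the fitted pipeline to new records: features are extracted for
#' the selected sources only, normalized with the training-set min/max,
#' merged in the stored rank order, reduced to the INCA-selected columns,
#' and classified by the final model trained on all training data.
#'
#' @param object a `"frustum154"` fit.
#' @param newdata a [grasp_dataset()], a list of [signal_record()]s, or a
#'   single record.
#' @param ... ignored.
#' @return Factor of predicted grasp classes.
#' @export
predict.frustum154 <- function(object, newdata, ...) {
  records <- if (inherits(newdata, "grasp_dataset")) newdata$records
             else if (inherits(newdata, "signal_record")) list(newdata)
             else newdata
  params_list <- object$config$params_list
  sel <- object$selected_sources
  rows <- lapply(records, function(r) {
    fv <- extract_all_feature_vectors(r, params_list)
    blocks <- lapply(seq_along(sel), function(k) {
      v <- fv[sel[k] + 1L, ]
      st <- object$source_stats[[k]]
      span <- st$hi - st$lo
      span[span == 0] <- 1
      (v - st$lo) / span
    })
    unlist(blocks)
  })
  Xnew <- do.call(rbind, rows)[, object$inca$selected_indices, drop = FALSE]
  predict(object$final_model, Xnew)
}

#' Write the artifacts of a fit to a directory
#'
#' Loss table and INCA curve as CSV, column provenance as CSV, the
#' evaluation report as JSON, and the confusion matrix as a plain-text
#' table.
#'
#' @param fit a `"frustum154"` object.
#' @param dir output directory (created if missing).
#' @return Invisibly, the written paths.
#' @export
write_frustum154_artifacts <- function(fit, dir) {
  stopifnot(inherits(fit, "frustum154"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    loss = file.path(dir, "loss_table.csv"),
    inca = file.path(dir, "inca_curve.csv"),
    prov = file.path(dir, "provenance.csv"),
    report = file.path(dir, "report.json"),
    confusion = file.path(dir, "confusion.txt"))
  lt <- as.data.frame(fit$loss_table)
  lt$selected <- lt$source_id %in% fit$selected_sources
  utils::write.csv(lt, paths["loss"], row.names = FALSE)
  utils::write.csv(data.frame(size = fit$inca$sizes,
                              loss = fit$inca$loss_curve),
                   paths["inca"], row.names = FALSE)
  utils::write.csv(fit$provenance, paths["prov"], row.names = FALSE)
  report_to_json(fit$report, paths["report"])
  utils::capture.output(print(fit$report), file = paths["confusion"])
  invisible(paths)
}
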
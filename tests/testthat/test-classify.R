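clouds <- function(n_per = 20, sep = 10, seed = 71) {
  y <- rep(unname(grasp_classes()), each = n_per)
  X <- frustum154:::with_seed(seed,
    matrix(rnorm(6 * n_per * 4), ncol = 4) +
      sep * outer(rep(1:6, each = n_per), c(1, -1, 0.5, 2)))
  list(X = X, y = y)
}

test_that("both classifier families separate far-apart class clouds", {
  d <- clouds()
  for (fam in c("knn", "svm")) {
    pred <- crossval_predict(d$X, d$y, classifier_spec(fam), folds = 10,
                             seed = 1)
    expect_equal(mean(pred == d$y), 1)
  }
})

test_that("cross-validation is stratified, exhaustive and deterministic", {
  d <- clouds()
  f <- stratified_folds(d$y, folds = 10, seed = 3)
  expect_equal(sort(unique(f)), 1:10)
  expect_true(all(table(d$y, f) == 2))  # 20 per class over 10 folds
  expect_error(stratified_folds(rep(c("C", "H"), c(3, 30)), folds = 10),
               "at most 3 folds")
  a <- crossval_predict(d$X, d$y, classifier_spec("knn"), 10, seed = 5)
  b <- crossval_predict(d$X, d$y, classifier_spec("knn"), 10, seed = 5)
  expect_identical(a, b)
})

test_that("label-permuted data scores at chance", {
  d <- clouds(sep = 0)
  yp <- frustum154:::with_seed(8, sample(d$y))
  pred <- crossval_predict(d$X, yp, classifier_spec("knn"), 10, seed = 1)
  expect_equal(mean(pred != yp), 5 / 6, tolerance = 0.1)
})

test_that("1-NN has zero training error on distinct points", {
  d <- clouds(n_per = 5, sep = 0)
  fit <- train_classifier(d$X, d$y, classifier_spec("knn"))
  expect_equal(as.character(predict(fit, d$X)), d$y)
})

test_that("evaluation metrics derive correctly from predictions", {
  rep0 <- suppressWarnings(evaluation_report(c("C", "H", "C"), c("C", "H", "H")))
  expect_equal(rep0$accuracy, 100 * 2 / 3)
  y <- rep(unname(grasp_classes()), each = 3)
  repid <- evaluation_report(y, y)
  expect_equal(repid$accuracy, 100)
  expect_equal(unname(repid$f1), rep(100, 6))
  expect_error(evaluation_report(character(0), character(0)), "nonempty")
  # a never-predicted class reports precision 0 with a warning
  expect_warning(repz <- evaluation_report(c("C", "H"), c("C", "C")),
                 "never predicted")
  expect_equal(unname(repz$precision[2]), 0)
})

test_that("reference confusion matrices reproduce the published metrics", {
  refs <- reference_confusions()
  expect_equal(vapply(refs, function(m) sum(m), numeric(1)),
               c(DB1 = 900, DB2 = 1800, DB3 = 2700))
  r1 <- evaluation_report(confusion = refs$DB1)
  expect_equal(r1$accuracy, 98.89, tolerance = 0.01 / 98.89)
  expect_equal(unname(r1$recall["T"]), 96.67, tolerance = 1e-4)
  expect_equal(unname(r1$precision["P"]), 97.39, tolerance = 1e-4)
  expect_equal(unname(r1$f1["S"]), 100)
  r2 <- evaluation_report(confusion = refs$DB2)
  expect_equal(r2$accuracy, 94.94, tolerance = 0.01 / 94.94)
  expect_equal(unname(r2$recall["S"]), 99.67, tolerance = 1e-4)
  r3 <- evaluation_report(confusion = refs$DB3)
  expect_equal(r3$accuracy, 95.30, tolerance = 0.01 / 95.30)
})

test_that("accuracy equals the support-weighted mean of class recalls", {
  refs <- reference_confusions()
  for (m in refs) {
    r <- evaluation_report(confusion = m)
    expect_equal(r$accuracy,
                 sum(r$recall * rowSums(m)) / sum(m))
  }
})

test_that("reports serialize to JSON with all metric fields", {
  r <- suppressWarnings(evaluation_report(c("C", "H"), c("C", "H")))
  js <- jsonlite::fromJSON(report_to_json(r))
  expect_equal(js$accuracy, 100)
  expect_named(js, c("confusion", "accuracy", "recall", "precision", "f1",
                     "macro_precision", "macro_recall", "macro_f1", "n"),
               ignore.order = TRUE)
})
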
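test_that("channel concatenation is length-additive and order-preserving", {
  expect_identical(concat_channels(c(1, 2), c(3, 4)), c(1, 2, 3, 4))
  expect_length(concat_channels(rnorm(3000), rnorm(3000)), 6000)
  expect_error(concat_channels(c(1, 2), c(3)), "same length")
  expect_error(concat_channels(numeric(0), numeric(0)), "nonempty")
  # injectivity on fixed lengths: distinct inputs give distinct outputs
  a <- concat_channels(c(1, 2), c(3, 4))
  b <- concat_channels(c(1, 3), c(2, 4))
  expect_false(identical(a, b))
})

test_that("signal records validate their inputs", {
  r <- signal_record(1:10, 11:20, fs = 500, label = "C")
  expect_s3_class(r, "signal_record")
  expect_error(signal_record(1:10, 1:9, label = "C"), "same length")
  expect_error(signal_record(1:10, 1:10, label = "X"), "grasp class")
})

test_that("synthetic generator is seed-reproducible with stable class counts", {
  a <- synth_dataset(n_per_class = 5, duration_s = 0.5, fs = 500, seed = 7)
  b <- synth_dataset(n_per_class = 5, duration_s = 0.5, fs = 500, seed = 7)
  expect_identical(a, b)
  expect_length(a, 30)
  expect_equal(as.integer(table(dataset_labels(a))), rep(5L, 6))
  # different seed: different samples, same label marginals
  c <- synth_dataset(n_per_class = 5, duration_s = 0.5, fs = 500, seed = 8)
  expect_false(identical(a$records[[1]]$ch1, c$records[[1]]$ch1))
  expect_equal(table(dataset_labels(a)), table(dataset_labels(c)))
  # caller RNG state is untouched
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(synth_dataset(2, 0.2, 500, seed = 1)); after <- rnorm(1)
  expect_identical(before, after)
  expect_error(synth_dataset(0, 1, 500, 1), "n_per_class")
  expect_error(synth_dataset(1, 0.01, 500, 1), "too short")
})

test_that("classes are spectrally separated enough for a 1-NN on moments", {
  ds <- synth_dataset(n_per_class = 12, duration_s = 1, fs = 500, seed = 3)
  X <- t(vapply(ds$records, function(r)
    statistical_features(concat_channels(r$ch1, r$ch2)), numeric(30)))
  y <- dataset_labels(ds)
  loss <- frustum154:::crossval_loss(minmax_normalize(X), y,
                                     classifier_spec("knn"), folds = 4, seed = 1)
  expect_lt(loss, 5 / 6 - 0.15)  # clearly above chance
})

test_that("dataset fusion sums records and per-class counts", {
  d1 <- synth_dataset(2, 0.2, 500, seed = 1)
  d2 <- synth_dataset(4, 0.2, 500, seed = 2)
  d3 <- build_db3(d1, d2)
  expect_length(d3, 36)
  expect_equal(as.integer(table(dataset_labels(d3))), rep(6L, 6))
  expect_equal(d3$name, "DB3")
  expect_error(build_db3(d1, grasp_dataset(d2$records[1:3], "x")),
               "class sets differ")
  d_fs <- synth_dataset(2, 0.2, fs = 1000, seed = 1)
  expect_error(build_db3(d1, d_fs), "sampling rates")
})

test_that("CSV round trip preserves a dataset's signals and labels", {
  ds <- synth_dataset(2, 0.2, 500, seed = 5)
  dir <- file.path(tempdir(), "csv_ds")
  write_dataset_csv(ds, dir)
  back <- read_dataset_csv(dir)
  expect_equal(length(back), length(ds))
  expect_equal(dataset_labels(back), dataset_labels(ds))
  expect_equal(back$records[[5]]$ch2, ds$records[[5]]$ch2, tolerance = 1e-12)
})
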
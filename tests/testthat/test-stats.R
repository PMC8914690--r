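test_that("elementary moments evaluate directly", {
  s <- statistical_features(c(1, 2, 3), kmax = 2)
  expect_length(s, 30)
  expect_equal(unname(s[c("mean_raw", "median_raw", "maximum_raw",
                          "minimum_raw", "range_raw", "energy_raw")]),
               c(2, 2, 3, 1, 2, 14))
  expect_equal(unname(s["rms_raw"]), sqrt(14 / 3))
  expect_error(statistical_features(1), "length >= 2")
})

test_that("nonnegative signals have identical raw and absolute halves", {
  x <- abs(rnorm(200)) + 0.1
  s <- statistical_features(x)
  expect_equal(unname(s[1:15]), unname(s[16:30]))
})

test_that("wavelet entropies follow their closed forms", {
  expect_equal(unname(wavelet_entropies(c(1, 1))["shannon"]), 0)
  expect_equal(unname(wavelet_entropies(c(exp(1), exp(1)))["log_energy"]), 4)
  expect_equal(unname(wavelet_entropies(c(0.1, 0.1), sure_eps = 3)["sure"]),
               2 - 2 + 0.02)
  # zero samples contribute nothing (0 * log 0 := 0, log 0 := 0)
  expect_equal(unname(wavelet_entropies(c(0, 2))["shannon"]), -4 * log(4))
  expect_equal(unname(wavelet_entropies(c(0, 2))["log_energy"]), log(4))
})

test_that("Higuchi dimension hits the known limits", {
  expect_equal(higuchi_fd(seq(0, 1, length.out = 1000), 10), 1, tolerance = 0.05)
  set.seed(13)
  expect_equal(higuchi_fd(rnorm(5000), 10), 2, tolerance = 0.15)
  expect_equal(higuchi_fd(rep(4, 100), 10), 1)
  expect_error(higuchi_fd(1:5, 10), "longer than kmax")
})

test_that("moment identities and shift invariance hold", {
  set.seed(14)
  x <- rnorm(500, sd = 2)
  s <- statistical_features(x)
  n <- length(x)
  expect_equal(unname(s["energy_raw"]), n * unname(s["rms_raw"])^2)
  expect_equal(unname(s["range_raw"]),
               unname(s["maximum_raw"] - s["minimum_raw"]))
  expect_equal(unname(s["sd_raw"])^2, unname(s["variance_raw"]))
  sh <- statistical_features(x + 100)
  keep <- c("variance_raw", "sd_raw", "range_raw", "kurtosis_raw",
            "skewness_raw")
  expect_equal(s[keep], sh[keep])
})

test_that("kurtosis and skewness use the Pearson population conventions", {
  set.seed(15)
  z <- rnorm(10000)
  s <- statistical_features(z)
  expect_equal(unname(s["kurtosis_raw"]), 3, tolerance = 0.15)
  expect_equal(unname(s["skewness_raw"]), 0, tolerance = 0.15)
})

test_that("the 30-feature order is frozen", {
  expect_equal(statistical_feature_names()[c(1, 4, 13, 16, 30)],
               c("mean_raw", "shannon_raw", "higuchi_raw", "mean_abs",
                 "rms_abs"))
  # golden vector: moments of a fixed tiny signal, each recomputed here
  # from its defining formula
  x <- c(-2, 0, 1, 3)
  s <- statistical_features(x, sure_eps = 3, kmax = 2)
  m2 <- mean((x - mean(x))^2)
  expected <- c(mean(x), median(x), var(x),
                -sum(x^2 * ifelse(x == 0, 0, log(x^2))),
                sum(ifelse(x == 0, 0, log(x^2))),
                max(x), min(x), sd(x), max(x) - min(x),
                4 - sum(abs(x) <= 3) + sum(pmin(x^2, 9)),
                mean((x - mean(x))^4) / m2^2,
                mean((x - mean(x))^3) / m2^1.5,
                higuchi_fd(x, 2), sum(x^2), sqrt(mean(x^2)))
  expect_equal(unname(s[1:15]), expected)
})
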
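test_that("ternary threshold is half the sample standard deviation", {
  expect_equal(compute_threshold(c(5, 5, 5, 5)), 0)
  expect_equal(compute_threshold(c(0, 2)), sqrt(2) / 2)
  # closed form for an arithmetic ramp: sample var of 1..n is n*(n+1)/12
  expect_equal(compute_threshold(1:49), sqrt(49 * 50 / 12) / 2)
  expect_equal(compute_threshold(1:49, sd_type = "population"),
               sqrt(49 * 50 / 12 * 48 / 49) / 2)
  expect_error(compute_threshold(3), "length >= 2")
})

test_that("ternary kernels fire strictly outside the [-d, d] band", {
  expect_equal(ternary_bits(5, 1, 2), list(upper = 1L, lower = 0L))
  expect_equal(ternary_bits(1, 5, 2), list(upper = 0L, lower = 1L))
  # boundary a - s = +/- d maps to (0, 0) in both kernels
  expect_equal(ternary_bits(3, 1, 2), list(upper = 0L, lower = 0L))
  expect_equal(ternary_bits(1, 3, 2), list(upper = 0L, lower = 0L))
})

test_that("overlapping blocks have stride 1 and length 49", {
  expect_equal(ncol(extract_blocks(rnorm(49))), 1)
  b <- extract_blocks(1:50)
  expect_equal(ncol(b), 2)
  expect_equal(b[, 2], 2:50)
  expect_error(extract_blocks(rnorm(48)), "at least 49")
})

test_that("blocks map row-major onto the 7x7 grid and back", {
  m <- block_to_matrix(1:49)
  expect_equal(m[1, 1], 1); expect_equal(m[1, 7], 7)
  expect_equal(m[2, 1], 8); expect_equal(m[7, 7], 49)
  expect_equal(as.vector(t(m)), 1:49)  # row-major round trip
  expect_true(all(block_to_matrix(rep(2, 49)) == 2))
  expect_error(block_to_matrix(1:48), "exactly 49")
})

test_that("graph encoding matches the hand-evaluated edge walks", {
  expect_equal(unname(encode_matrix(matrix(1, 7, 7), 0)), rep(0L, 6))
  # ramp block, d = 0.5: derived by walking the printed edge pairs by hand
  expect_equal(unname(encode_matrix(block_to_matrix(1:49), 0.5)),
               c(56, 7, 56, 7, 28, 35))
  # bit weighting: a single spike at grid cell (1,2) touches bottom edge 1
  # (weight 2^0, upper kernel), bottom edge 6 (weight 2^5, lower kernel) and
  # connection edge 1 (weight 2^0, upper kernel)
  m <- matrix(0, 7, 7); m[1, 2] <- 100
  expect_equal(unname(encode_matrix(m, 5)), c(1, 32, 0, 0, 1, 0))
})

test_that("vectorized map signals equal the naive per-block oracle", {
  set.seed(41)
  for (len in c(49, 50, 120, 500)) {
    x <- rnorm(len)
    v <- map_signals(x)
    ref <- naive_map_signals(x, compute_threshold(x))
    expect_equal(do.call(rbind, v), ref, ignore_attr = TRUE)
  }
  # constant signal: all codes zero
  v0 <- map_signals(rep(3, 100))
  expect_true(all(vapply(v0, function(m) all(m == 0L) && length(m) == 52,
                         logical(1))))
})

test_that("frustum features are conserved, bounded, and affine-invariant", {
  set.seed(42)
  x <- rnorm(300)
  fv <- frustum_features(x)
  expect_length(fv, 384)
  expect_equal(as.vector(tapply(fv, rep(1:6, each = 64), sum)), rep(252, 6))
  # constant signal concentrates each histogram in code 0
  fvc <- frustum_features(rep(1.5, 100))
  expect_equal(unname(fvc[seq(1, 384, by = 64)]), rep(52L, 6))
  expect_equal(sum(fvc), 6 * 52)
  # positive affine transforms leave the pattern unchanged
  expect_identical(frustum_features(3 * x + 10), fv)
  # negation swaps the upper/lower kernel histograms of each graph
  swap <- c(65:128, 1:64, 193:256, 129:192, 321:384, 257:320)
  expect_equal(unname(frustum_features(-x)), unname(fv[swap]))
})
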
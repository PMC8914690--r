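default_sets <- list(c(1, 2, 6), c(2, 4, 24), c(3, 6, 46), c(4, 8, 73))

test_that("parameter derivation and validation follow the Q/r/J rules", {
  p <- tqwt_params(1, 2, 6)
  expect_equal(p$beta, 1)
  expect_equal(p$alpha, 0.5)
  p4 <- tqwt_params(4, 8, 73)
  expect_equal(p4$beta, 0.4)
  expect_equal(p4$alpha, 0.95)
  expect_error(tqwt_params(0.5, 2, 6))
  expect_error(tqwt_params(1, 1, 6))
  expect_error(tqwt_params(1, 2, 0))
  expect_gte(tqwt_jmax(6000, p4), 73)
  expect_lt(tqwt_jmax(512, p), 9)
})

test_that("band counts are J + 1 for each parameterization (7/25/47/74)", {
  set.seed(21)
  x <- rnorm(6000)
  counts <- vapply(default_sets, function(q)
    length(tqwt_decompose(x, tqwt_params(q[1], q[2], q[3]))$bands), integer(1))
  expect_equal(counts, c(7L, 25L, 47L, 74L))
  expect_equal(sum(counts), 153L)
  m <- multi_tqwt(x)
  expect_length(m$bands, 153)
  expect_equal(nrow(m$provenance), 153)
})

test_that("perfect reconstruction holds across all parameter sets", {
  set.seed(22)
  for (q in default_sets) {
    p <- tqwt_params(q[1], q[2], q[3])
    x <- rnorm(6000)
    sb <- tqwt_decompose(x, p)
    xr <- tqwt_reconstruct(sb)
    expect_lt(max(abs(x - xr)) / max(abs(x)), 1e-8)
  }
  # odd length: padding is transparent
  x <- rnorm(501)
  sb <- tqwt_decompose(x, tqwt_params(1, 2, 3))
  expect_true(sb$padded)
  expect_equal(tqwt_reconstruct(sb), x, tolerance = 1e-10)
})

test_that("the frame is Parseval-tight and linear", {
  set.seed(23)
  for (q in default_sets) {
    p <- tqwt_params(q[1], q[2], q[3])
    x <- rnorm(6000)
    sb <- tqwt_decompose(x, p)
    e <- sum(vapply(sb$bands, function(b) sum(b^2), numeric(1)))
    expect_equal(e, sum(x^2), tolerance = 1e-6)
  }
  # linearity, bandwise
  p <- tqwt_params(2, 4, 10)
  x <- rnorm(1000); y <- rnorm(1000)
  sxy <- tqwt_decompose(2 * x - 3 * y, p)
  sx <- tqwt_decompose(x, p); sy <- tqwt_decompose(y, p)
  for (j in seq_along(sxy$bands))
    expect_equal(sxy$bands[[j]], 2 * sx$bands[[j]] - 3 * sy$bands[[j]],
                 tolerance = 1e-9)
  # zero in, zero out
  s0 <- tqwt_decompose(numeric(1000), p)
  expect_true(all(vapply(s0$bands, function(b) all(b == 0), logical(1))))
})

test_that("a pass-band-supported low-pass band reconstructs at equal energy", {
  # the synthesis of a single band preserves energy exactly when the band's
  # spectrum avoids the transition region; a constant (DC) band is the
  # canonical such case, and its reconstruction is maximally smooth
  p <- tqwt_params(2, 4, 8)
  sb <- tqwt_decompose(rnorm(512), p)
  for (j in 1:8) sb$bands[[j]][] <- 0
  sb$bands[[9]] <- rep(1, length(sb$bands[[9]]))
  xr <- tqwt_reconstruct(sb)
  expect_equal(sum(xr^2), sum(sb$bands[[9]]^2), tolerance = 1e-6)
  expect_lt(max(abs(diff(xr))), 1e-12)
})

test_that("level-depth violations are rejected by name", {
  p <- tqwt_params(1, 2, 12)
  expect_error(tqwt_decompose(rnorm(512), p), "J = 12 exceeds J_max = 6")
  expect_error(tqwt_decompose(rnorm(6), tqwt_params(1, 2, 1)), "length >= 8")
})
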
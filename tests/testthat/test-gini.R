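test_that("gini reproduces hand-computed reference values", {
  expect_equal(gini(c(1, 1, 1, 1)), 0)
  expect_equal(gini(c(1, 0, 0, 0)), 0.75) # (N - 1) / N
  expect_equal(gini(c(3, 1)), 0.25)
  expect_error(gini(c(0, 0, 0)), "degenerate")
  expect_true(is.na(gini(c(0, 0), degenerate = "na")))
})

test_that("sorted-array gini equals the double-sum definition", {
  set.seed(11)
  for (i in 1:50) {
    x <- rexp(sample(2:40, 1))
    expect_equal(gini(x), oracle_gini_double_sum(x), tolerance = 1e-12)
    expect_equal(gini(x, method = "pairwise"), gini(x), tolerance = 1e-12)
  }
})

test_that("gini is scale- and permutation-invariant and bounded", {
  set.seed(12)
  for (i in 1:20) {
    x <- rexp(sample(3:30, 1))
    g <- gini(x)
    for (c in c(1e-6, 1, 1e6)) {
      expect_equal(gini(c * x), g, tolerance = 1e-12)
    }
    expect_equal(gini(sample(x)), g, tolerance = 1e-12)
    expect_gte(g, 0)
    expect_lte(g, (length(x) - 1) / length(x))
  }
})

test_that("transferring power from a poorer to a richer bin never lowers gini", {
  set.seed(13)
  for (i in 1:50) {
    x <- rexp(10)
    o <- order(x)
    poor <- o[1]; rich <- o[10]
    delta <- runif(1, 0, x[poor])
    y <- x
    y[poor] <- y[poor] - delta
    y[rich] <- y[rich] + delta
    expect_gte(gini(y), gini(x) - 1e-12)
  }
})

test_that("spectral gini equals gini of the in-band powers", {
  set.seed(14)
  p <- fake_spectrum(rexp(256), fs = 128)
  b <- band_indices(128, 256, 4, 40)
  expect_equal(spectral_gini(p, b), gini(p$power[b$idx]))
  expect_equal(spectral_gini(normalize_spectrum(p, b), b),
               spectral_gini(p, b), tolerance = 1e-12)
})

test_that("threshold calibration averages baseline in-band bin power", {
  b <- band_indices(10, 5, 2, 4)
  p1 <- fake_spectrum(c(99, 10, 10, 99, 99), fs = 10)
  expect_equal(calibrate_threshold(list(p1), b, 0.02), 0.2)
  p2 <- fake_spectrum(c(99, 30, 30, 99, 99), fs = 10)
  expect_equal(calibrate_threshold(list(p1, p2), b, 0.02), 0.4)
  expect_equal(calibrate_threshold(list(p1, p2), b, 0.04), 0.8) # linear
  expect_error(calibrate_threshold(list(), b), "at least one")
})

test_that("binarization is strict at the threshold boundary", {
  b <- band_indices(10, 5, 2, 4)
  p <- fake_spectrum(c(0, 0.1, 5, 0, 0), fs = 10)
  expect_identical(binarize_spectrum(p, b, 1)$bits, c(0L, 1L))
  p_eq <- fake_spectrum(c(0, 1, 2, 0, 0), fs = 10)
  expect_identical(binarize_spectrum(p_eq, b, 1)$bits, c(0L, 1L)) # == alpha -> 0
  p_all <- fake_spectrum(c(0, 1, 2, 0, 0), fs = 10)
  expect_identical(binarize_spectrum(p_all, b, 0)$bits, c(1L, 1L))
})

test_that("bspg closed form matches the double sum exhaustively and at random", {
  for (n in c(2, 5, 9, 12)) {
    grid <- expand.grid(rep(list(0:1), n))
    for (r in seq_len(nrow(grid))) {
      bits <- as.numeric(grid[r, ])
      if (all(bits == 0)) next # 0/0 in the double sum; convention tested below
      expect_equal(bspg(bits), oracle_bspg_double_sum(bits))
      expect_equal(bspg(bits, method = "pairwise"), bspg(bits))
    }
  }
  set.seed(15)
  for (i in 1:1000) {
    bits <- rbinom(sample(2:200, 1), 1, runif(1, 0.05, 0.95))
    if (all(bits == 0)) bits[1] <- 1
    expect_equal(bspg(bits), oracle_bspg_double_sum(bits))
  }
})

test_that("bspg handles the degenerate and saturated spectra by convention", {
  expect_warning(v <- bspg(rep(0, 8)), "below threshold")
  expect_equal(v, 1)
  expect_equal(bspg(rep(1, 8)), 0)
})
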
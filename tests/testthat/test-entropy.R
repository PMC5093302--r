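test_that("spectral entropy hits its limiting values", {
  b <- band_indices(64, 64, 2, 30)
  nb <- length(b$idx)
  one <- rep(0, 64); one[b$idx[3]] <- 5
  expect_equal(spectral_entropy(fake_spectrum(one, 64), b), 0)
  expect_equal(spectral_entropy(fake_spectrum(rep(2.5, 64), 64), b), 1)
  two <- rep(0, 64); two[b$idx[c(1, nb)]] <- 7
  expect_equal(spectral_entropy(fake_spectrum(two, 64), b), log(2) / log(nb))
})

test_that("spectral entropy rejects a single-bin band", {
  p <- fake_spectrum(rep(1, 64), 64)
  b1 <- band_indices(64, 64, 2, 2.5) # one bin
  expect_error(spectral_entropy(p, b1), "two bins")
})

test_that("ordinal patterns: monotone series collapse to the identity pattern", {
  for (m in 2:4) {
    for (tau in 1:2) {
      od <- ordinal_distribution(seq_len(30), m = m, tau = tau)
      expect_equal(sum(od$probs), 1)
      ident <- which(apply(od$patterns, 1, function(r) all(r == seq_len(m))))
      expect_equal(od$probs[ident], 1)
    }
  }
})

test_that("ordinal pattern of [3,1,2] is the single correct permutation", {
  od <- ordinal_distribution(c(3, 1, 2), m = 3, tau = 1)
  expect_equal(sum(od$counts), 1)
  hit <- od$patterns[which(od$counts == 1), ]
  expect_equal(as.numeric(hit), c(3, 1, 2)) # x1 highest, x2 lowest, x3 middle
})

test_that("ordinal distributions sum to one on random series (with ties)", {
  set.seed(21)
  for (i in 1:20) {
    x <- sample(1:5, 50, replace = TRUE) # heavy ties
    od <- ordinal_distribution(x, m = 3, tau = sample(1:3, 1))
    expect_equal(sum(od$probs), 1)
    expect_true(all(od$counts >= 0))
  }
  expect_error(ordinal_distribution(c(1, 2), m = 3, tau = 2), "too short")
})

test_that("permutation entropy: ramp gives 0, white noise approaches 1", {
  expect_equal(permutation_entropy(seq_len(200)), 0)
  set.seed(22)
  x <- rnorm(1e5)
  expect_lt(abs(permutation_entropy(x) - 1), 0.01)
})

test_that("permutation entropy is invariant under positive affine maps", {
  set.seed(23)
  x <- rnorm(500)
  expect_equal(permutation_entropy(3.2 * x + 17), permutation_entropy(x))
})

test_that("the alternative normalization and extended embedding are exposed", {
  set.seed(24)
  x <- rnorm(500)
  pe_a <- permutation_entropy(x)
  pe_b <- permutation_entropy(x, normalization = "log_mp1fact_half")
  expect_equal(pe_b / pe_a, 2 * log(6) / log(12), tolerance = 1e-12)
  pe_ext <- permutation_entropy(x, embedding = "extended")
  expect_true(is.finite(pe_ext) && pe_ext >= 0 && pe_ext <= 1)
})

test_that("approximate entropy limiting cases: constant and periodic series", {
  expect_equal(approximate_entropy(rep(5, 200), n_samples = 200), 0)
  x <- rep(c(1, 2), 100)
  ae <- approximate_entropy(x, m = 2, r_factor = 0.1 / sd(x),
                            n_samples = 200)
  expect_equal(ae, oracle_apen(x, 2, 0.1), tolerance = 1e-9)
  expect_lt(abs(ae), 1e-3)
})

test_that("approximate entropy matches the brute-force definition exactly", {
  set.seed(25)
  for (i in 1:50) {
    x <- rnorm(200)
    r <- 0.2 * sd(x)
    expect_equal(approximate_entropy(x, m = 2, r_factor = 0.2,
                                     n_samples = 200),
                 oracle_apen(x, 2, r), tolerance = 1e-10)
  }
})

test_that("noise carries more approximate entropy than a matched sinusoid", {
  set.seed(26)
  t <- (0:1023) / 256
  wins <- replicate(100, {
    noise <- rnorm(1024)
    tone <- sqrt(2) * sin(2 * pi * 7 * t + runif(1, 0, 2 * pi))
    approximate_entropy(noise) > approximate_entropy(tone)
  })
  expect_true(all(wins))
})
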
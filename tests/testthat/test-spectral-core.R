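test_that("low-pass filter passes DC, keeps length, rejects bad cutoffs", {
  rec <- recording(rep(3.7, 2560), fs = 256)
  out <- lowpass_filter(rec)
  expect_length(out$samples, 2560)
  expect_lt(max(abs(out$samples - 3.7)), 1e-9)
  expect_error(lowpass_filter(rec, cutoff = 128), "Nyquist")
})

test_that("a 60 Hz tone is attenuated below 1% RMS by the default filter", {
  t <- (0:25599) / 256
  rec <- recording(sin(2 * pi * 60 * t), fs = 256)
  out <- lowpass_filter(rec)
  expect_lt(sd(out$samples) / sd(rec$samples), 0.01)
})

test_that("epoch_stream counts and tiling match the stepping arithmetic", {
  rec <- recording(rnorm(256 * 60), fs = 256)
  eps <- epoch_stream(rec, 10, 5)
  expect_length(eps, 11) # floor((60 - 10) / 5) + 1
  expect_equal(vapply(eps, function(e) e$start_time, numeric(1)),
               seq(0, 50, by = 5))
  expect_true(all(vapply(eps, function(e) length(e$samples),
                         integer(1)) == 2560L))

  expect_length(epoch_stream(recording(rnorm(2560), 256), 10, 5), 1)
  expect_warning(short <- epoch_stream(recording(rnorm(256 * 9), 256), 10, 5),
                 "shorter")
  expect_length(short, 0)
})

test_that("power spectrum concentrates an integer-bin cosine and is zero for silence", {
  expect_equal(power_spectrum(rep(0, 64), fs = 256)$power, rep(0, 64))

  n <- 1280
  x <- cos(2 * pi * 32 * (0:(n - 1)) / 256)
  ps <- power_spectrum(x, window = "rectangular", fs = 256)
  k_tone <- 32 / 256 * n + 1 # 1-based bin at 32 Hz
  peak <- ps$power[k_tone]
  off <- ps$power[-c(k_tone, n - k_tone + 2)]
  expect_lt(max(off), 1e-9 * peak)
})

test_that("power spectrum satisfies Parseval for random signals and both windows", {
  set.seed(42)
  for (window in c("blackman", "rectangular")) {
    for (rep in 1:5) {
      x <- rnorm(512)
      ps <- power_spectrum(x, window = window, fs = 128)
      w <- if (window == "blackman") docgini:::blackman_window(512) else rep(1, 512)
      expect_equal(sum(ps$power), 512 * sum((w * x)^2), tolerance = 1e-6)
    }
  }
})

test_that("spectrum normalization rescales band power to unit sum", {
  p <- fake_spectrum(c(1, 2, 2, 4, 9), fs = 10)
  b <- band_indices(10, 5, 2, 4) # bins 2..4 (0-based 1..2? closed band)
  pn <- normalize_spectrum(p, b)
  expect_equal(sum(pn$power), 1, tolerance = 1e-12)
  expect_equal(normalize_spectrum(pn, b)$power, pn$power) # idempotent
  expect_error(normalize_spectrum(fake_spectrum(rep(0, 5), 10), b),
               "degenerate")
})

test_that("band powers [2,2,4] normalize to [0.25,0.25,0.5]", {
  p <- fake_spectrum(c(7, 2, 2, 4, 7, 7), fs = 12)
  b <- band_indices(12, 6, 2, 6) # bins at 2, 4, 6 Hz
  expect_equal(normalize_spectrum(p, b)$power, c(0.25, 0.25, 0.5))
})

test_that("band indices reproduce the reference 13-40 Hz example", {
  b <- band_indices(256, 1280, 13, 40)
  expect_identical(b$L, 66L)
  expect_identical(b$H, 201L)
  full <- band_indices(256, 1280, 0, 128)
  expect_identical(full$L, 1L)
  expect_identical(full$H, 641L) # N/2 + 1
})

test_that("band indices agree with brute-force bin enumeration", {
  set.seed(7)
  for (i in 1:1000) {
    fs <- runif(1, 32, 1024)
    n <- sample(16:4096, 1)
    f_low <- runif(1, 0, fs / 4)
    f_high <- runif(1, f_low + fs / 16, fs / 2)
    freq <- (0:(n - 1)) * fs / n
    keep <- which(freq >= f_low & freq <= f_high)
    if (!length(keep)) {
      expect_error(band_indices(fs, n, f_low, f_high))
    } else {
      b <- band_indices(fs, n, f_low, f_high)
      expect_identical(b$idx, keep)
      expect_identical(b$H - b$L + 1L, length(keep))
    }
  }
})
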
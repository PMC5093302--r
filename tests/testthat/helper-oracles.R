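# Independent oracles: literal, definition-level implementations used only
# to check the package's faster paths.

# Gini by the explicit double loop over all ordered pairs.
oracle_gini_double_sum <- function(x) {
  n <- length(x)
  acc <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      acc <- acc + abs(x[i] - x[j])
    }
  }
  acc / (2 * n * sum(x))
}

# BSpG by the same double loop on a 0/1 vector (NaN when all zero).
oracle_bspg_double_sum <- function(bits) {
  oracle_gini_double_sum(bits)
}

# Approximate entropy straight from the definition: embedded vectors,
# Chebyshev distances via pmax over coordinate-difference matrices,
# self-matches included.
oracle_apen <- function(x, m, r) {
  phi <- function(mm) {
    nv <- length(x) - mm + 1
    d <- matrix(0, nv, nv)
    for (k in 0:(mm - 1)) {
      seg <- x[(1 + k):(nv + k)]
      d <- pmax(d, abs(outer(seg, seg, "-")))
    }
    cc <- rowSums(d <= r) / nv
    mean(log(cc))
  }
  phi(m) - phi(m + 1)
}

# Somers' D by exhaustive pair enumeration.
oracle_somers_d <- function(y, x) {
  n <- length(y)
  conc <- disc <- untied_x <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i])
      dy <- sign(y[j] - y[i])
      if (dx != 0) {
        untied_x <- untied_x + 1
        if (dx * dy > 0) conc <- conc + 1
        if (dx * dy < 0) disc <- disc + 1
      }
    }
  }
  (conc - disc) / untied_x
}

# Spearman's rho from its definition: mid-ranks then the hand Pearson
# formula.
oracle_spearman <- function(y, x) {
  ry <- rank(y); rx <- rank(x)
  num <- sum((ry - mean(ry)) * (rx - mean(rx)))
  num / sqrt(sum((ry - mean(ry))^2) * sum((rx - mean(rx))^2))
}

# Build a doc_spectrum directly from a power vector (the documented fields
# of the class), for tests that need exact bin powers.
fake_spectrum <- function(power, fs, n = length(power)) {
  structure(list(power = power, fs = fs, n = n, normalized = FALSE,
                 window = "rectangular"),
            class = "doc_spectrum")
}

# A small cosine-mixture recording with a period dividing the epoch step,
# so every epoch sees an identical waveform.
periodic_recording <- function(minutes = 2, fs = 256) {
  t <- (0:(minutes * 60 * fs - 1)) / fs
  recording(2 * cos(2 * pi * 10 * t) + cos(2 * pi * 4 * t), fs)
}
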
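#' Detrended fluctuation analysis exponent
#'
#' Integrates the mean-removed series, splits the profile into
#' non-overlapping segments of length `n`, removes a per-segment linear
#' trend, and measures the RMS fluctuation `F(n)` about the trend; the
#' scaling exponent `alpha` is the least-squares slope of `log F` versus
#' `log n`. The default segment lengths span 6.7-157.8 ms (2-40 samples at
#' 256 Hz), log-spaced.
#'
#' White noise scales with `alpha ~ 0.5`, its running sum with
#' `alpha ~ 1.5`; anesthesia shifts the EEG toward the latter.
#'
#' @param x A `doc_epoch` or numeric vector.
#' @param n_min_s,n_max_s Segment-length range in seconds (defaults 0.0067
#'   and 0.1578).
#' @param fs Sampling rate, required for a bare vector.
#' @param n_scales Number of log-spaced segment lengths requested
#'   (default 12; duplicates after rounding are dropped).
#'
#' @return A `doc_dfa`: list with `segment_lengths`, `F` (RMS fluctuations),
#'   `alpha`, and `curve` (a tibble of `n`, `F`).
#' @examples
#' d <- dfa_exponent(rnorm(4096), fs = 256)
#' d$alpha
#' @export
dfa_exponent <- function(x, n_min_s = 0.0067, n_max_s = 0.1578, fs = NULL,
                         n_scales = 12) {
  if (inherits(x, "doc_epoch")) fs <- x$fs
  if (is.null(fs)) abort("`fs` required when `x` is a bare vector")
  x <- epoch_samples(x)
  # n = 2 is degenerate (a line interpolates 2 points, F = 0), so the
  # smallest usable segment is 3 samples.
  n_lo <- max(3L, as.integer(ceiling(n_min_s * fs)))
  n_hi <- as.integer(floor(n_max_s * fs))
  if (n_hi < n_lo) abort("segment-length range is empty at this fs")
  scales <- unique(round(exp(seq(log(n_lo), log(n_hi),
                                 length.out = n_scales))))
  scales <- scales[scales >= 3 & scales <= floor(length(x) / 4)]
  if (length(scales) < 3) {
    abort("fewer than 3 usable segment lengths; epoch too short")
  }
  prof <- cumsum(x - mean(x))
  fl <- vapply(scales, function(n) dfa_fluctuation(prof, n), numeric(1))
  alpha <- fit_dfa_slope(scales, fl)
  structure(list(segment_lengths = scales, F = fl, alpha = alpha,
                 curve = tibble::tibble(n = scales, F = fl)),
            class = "doc_dfa")
}

# RMS residual about per-segment linear trends, segments of length n tiled
# from the start of the profile (trailing remainder unused).
dfa_fluctuation <- function(prof, n) {
  nseg <- floor(length(prof) / n)
  y <- matrix(prof[seq_len(nseg * n)], nrow = n)
  t <- seq_len(n)
  xc <- t - mean(t)
  # per-segment OLS line: intercept = colMeans, slope = (xc'y)/(xc'xc)
  beta <- colSums(xc * y) / sum(xc * xc)
  res <- y - rep(colMeans(y), each = n) - outer(xc, beta)
  sqrt(mean(res^2))
}

fit_dfa_slope <- function(n, f) {
  unname(coef(lm(log(f) ~ log(n)))[2])
}

#' @export
print.doc_dfa <- function(x, ...) {
  cat(sprintf("<doc_dfa> alpha = %.3f over n = %d..%d (%d scales)\n",
              x$alpha, min(x$segment_lengths), max(x$segment_lengths),
              length(x$segment_lengths)))
  invisible(x)
}
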
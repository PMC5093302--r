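#' Gini coefficient of a nonnegative vector
#'
#' The mean absolute difference between all ordered pairs, normalized by
#' twice the mean: `G = sum_ij |x_i - x_j| / (2 N sum_i x_i)`. Zero for a
#' constant vector; `(N - 1) / N` when a single element carries everything
#' (approaching 1 as N grows). Scale- and permutation-invariant.
#'
#' The default evaluation uses the sorted-array identity
#' `G = (2 * sum_i i * x_(i)) / (N * sum x) - (N + 1) / N`, which is
#' O(N log N); `method = "pairwise"` evaluates the defining O(N^2) double sum
#' directly.
#'
#' @param x Nonnegative numeric vector with at least one positive element.
#' @param method `"sorted"` (default) or `"pairwise"`.
#' @param degenerate What to do when `sum(x) == 0`: `"error"` (default) or
#'   `"na"` to return `NA_real_` (useful mid-pipeline).
#'
#' @return A scalar in `[0, (N-1)/N]`.
#' @examples
#' gini(c(1, 1, 1, 1)) # 0
#' gini(c(1, 0, 0, 0)) # 0.75
#' @export
gini <- function(x, method = c("sorted", "pairwise"),
                 degenerate = c("error", "na")) {
  method <- match.arg(method)
  degenerate <- match.arg(degenerate)
  x <- as.numeric(x)
  if (!length(x)) abort("`x` is empty")
  if (!all(is.finite(x))) abort("`x` must be finite")
  if (any(x < 0)) abort("`x` must be nonnegative")
  s <- sum(x)
  if (s <= 0) {
    if (degenerate == "na") return(NA_real_)
    abort("degenerate input: all values are zero")
  }
  n <- length(x)
  g <- if (method == "sorted") {
    xs <- sort(x)
    (2 * sum(seq_len(n) * xs)) / (n * s) - (n + 1) / n
  } else {
    sum(abs(outer(x, x, "-"))) / (2 * n * s)
  }
  max(0, g) # guard against -eps from cancellation on near-equal inputs
}

#' Spectral Gini index (SpG)
#'
#' The Gini coefficient of the in-band power-spectrum values: 0 for a flat
#' spectrum, approaching 1 as power concentrates in few bins. Deepening
#' propofol anesthesia concentrates EEG power into the low-frequency bands,
#' so SpG rises with hypnotic depth.
#'
#' @param p A `doc_spectrum` from [power_spectrum()] (raw or normalized over
#'   the same band; SpG is scale-invariant so either gives the same value).
#' @param band A `doc_band` from [band_indices()].
#' @inheritParams gini
#'
#' @return A scalar in `[0, 1)`.
#' @export
spectral_gini <- function(p, band, degenerate = c("error", "na")) {
  pw <- if (isTRUE(p$normalized)) p$power else band_power(p, band)
  gini(pw, degenerate = match.arg(degenerate))
}

#' Calibrate the binarization threshold
#'
#' The BSpG threshold `alpha` is proportional to the average pre-infusion
#' power: `fraction` (default 2%) times the mean over baseline epochs of the
#' mean in-band bin power.
#'
#' @param baseline A list of `doc_spectrum` objects from epochs recorded
#'   before infusion start.
#' @param band A `doc_band`.
#' @param fraction Proportionality constant, `0 < fraction < 1`
#'   (default 0.02).
#'
#' @return The threshold `alpha`, in the same units as the spectral power.
#' @export
calibrate_threshold <- function(baseline, band, fraction = 0.02) {
  if (inherits(baseline, "doc_spectrum")) baseline <- list(baseline)
  if (!length(baseline)) abort("`baseline` must contain at least one epoch")
  if (!(fraction > 0 && fraction < 1)) {
    abort("`fraction` must be in (0, 1)")
  }
  per_epoch <- vapply(baseline, function(p) mean(band_power(p, band)),
                      numeric(1))
  fraction * mean(per_epoch)
}

#' Binarize a spectrum against a threshold
#'
#' Bin `k` maps to 1 when its power strictly exceeds `alpha`, else 0
#' (boundary power equal to `alpha` maps to 0).
#'
#' @param p A `doc_spectrum` (raw powers).
#' @param band A `doc_band`.
#' @param alpha Nonnegative power threshold from [calibrate_threshold()].
#'
#' @return A `doc_binarized`: list with `bits` (0/1 over the band), `alpha`,
#'   `band`.
#' @export
binarize_spectrum <- function(p, band, alpha) {
  if (alpha < 0) abort("`alpha` must be nonnegative")
  bits <- as.integer(band_power(p, band) > alpha)
  structure(list(bits = bits, alpha = alpha, band = band),
            class = "doc_binarized")
}

#' Binarized spectral Gini index (BSpG)
#'
#' The Gini coefficient of the binarized spectrum. With `N` band bins of
#' which `M` are zero (sub-threshold), the pairwise double sum collapses to
#' `M / N`: the fraction of spectral components suppressed below the
#' baseline-derived threshold. This makes BSpG extremely cheap while
#' tracking the same spectral concentration as SpG.
#'
#' `method = "pairwise"` evaluates the defining double sum instead of the
#' closed form. The all-zero case (`M = N`, a 0/0 in the closed form) is
#' defined as 1 — the limit of maximal suppression — with a warning.
#'
#' @param b A `doc_binarized` from [binarize_spectrum()], or a bare 0/1
#'   vector.
#' @param method `"closed_form"` (default, `M / N`) or `"pairwise"`.
#'
#' @return A scalar in `[0, 1]`.
#' @examples
#' bspg(c(rep(1, 12), rep(0, 88))) # 0.88
#' @export
bspg <- function(b, method = c("closed_form", "pairwise")) {
  method <- match.arg(method)
  bits <- if (inherits(b, "doc_binarized")) b$bits else as.numeric(b)
  if (!length(bits)) abort("empty binarized spectrum")
  if (!all(bits %in% c(0, 1))) abort("`bits` must be 0/1")
  n <- length(bits)
  m <- sum(bits == 0)
  if (m == n) {
    warn("all spectral components below threshold; BSpG defined as 1")
    return(1)
  }
  if (method == "closed_form") {
    m / n
  } else {
    sum(abs(outer(bits, bits, "-"))) / (2 * n * sum(bits))
  }
}
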
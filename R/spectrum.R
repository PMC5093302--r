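#' Power spectrum of an epoch
#'
#' Tapers the epoch (Blackman window by default, to limit spectral leakage),
#' takes the N-point DFT with N equal to the epoch sample count, and returns
#' the raw power `|X(f_k)|^2` at every DFT bin `k`. Bin `k` (1-based) sits at
#' frequency `(k - 1) * fs / N`.
#'
#' @param e A `doc_epoch` (from [epoch_stream()]) or numeric vector.
#' @param window `"blackman"` (default) or `"rectangular"`.
#' @param fs Sampling rate, required when `e` is a bare vector.
#' @param demean Subtract the epoch mean before windowing (default `FALSE`).
#'
#' @return A `doc_spectrum`: list with `power` (length N, all bins), `fs`,
#'   `n`, `normalized = FALSE`, `window`.
#' @examples
#' e <- sin(2 * pi * 32 * (0:1279) / 256)
#' ps <- power_spectrum(e, window = "rectangular", fs = 256)
#' which.max(ps$power[1:641]) # bin 161 <-> 32 Hz
#' @export
power_spectrum <- function(e, window = c("blackman", "rectangular"),
                           fs = NULL, demean = FALSE) {
  window <- match.arg(window)
  x <- epoch_samples(e)
  if (inherits(e, "doc_epoch")) fs <- e$fs
  if (is.null(fs)) abort("`fs` required when `e` is a bare vector")
  if (!length(x)) abort("epoch is empty")
  if (!all(is.finite(x))) abort("epoch contains non-finite samples")
  if (demean) x <- x - mean(x)
  n <- length(x)
  w <- switch(window,
              blackman = blackman_window(n),
              rectangular = rep(1, n))
  pw <- Mod(fft(w * x))^2
  structure(list(power = pw, fs = fs, n = n, normalized = FALSE,
                 window = window),
            class = "doc_spectrum")
}

# Classic three-term Blackman taper (a0 = 0.42, a1 = 0.5, a2 = 0.08),
# symmetric form.
blackman_window <- function(n) {
  if (n == 1) return(1)
  m <- 0:(n - 1)
  0.42 - 0.5 * cos(2 * pi * m / (n - 1)) + 0.08 * cos(4 * pi * m / (n - 1))
}

#' @export
print.doc_spectrum <- function(x, ...) {
  cat(sprintf("<doc_spectrum> N = %d @ %g Hz, window = %s%s\n",
              x$n, x$fs, x$window,
              if (isTRUE(x$normalized)) ", normalized" else ""))
  invisible(x)
}

#' Frequency band as DFT bin indices
#'
#' Maps a frequency band to the 1-based DFT bin indices `L..H` whose bin
#' frequencies `(k - 1) * fs / N` fall inside the closed interval
#' `[f_low, f_high]`. With `fs = 256`, `N = 1280` (a 5 s epoch) the 13-40 Hz
#' band gives `L = 66`, `H = 201`. The equivalent 0-based offsets are exposed
#' as `k0`.
#'
#' @param fs Sampling rate (Hz).
#' @param n DFT length.
#' @param f_low,f_high Band edges in Hz, `0 <= f_low < f_high <= fs/2`.
#'
#' @return A `doc_band`: list with `L`, `H` (1-based), `idx` (1-based bin
#'   indices `L:H`), `k0` (0-based), `freq` (bin frequencies), `f_low`,
#'   `f_high`.
#' @examples
#' band_indices(256, 1280, 13, 40)[c("L", "H")]
#' @export
band_indices <- function(fs, n, f_low, f_high) {
  if (n < 2) abort("`n` must be >= 2")
  if (!(f_low >= 0 && f_low < f_high && f_high <= fs / 2)) {
    abort("band must satisfy 0 <= f_low < f_high <= fs/2")
  }
  k0 <- 0:(n - 1)
  freq <- k0 * fs / n
  keep <- which(freq >= f_low & freq <= f_high)
  if (!length(keep)) abort("no DFT bin falls inside the requested band")
  structure(list(L = keep[1], H = keep[length(keep)], idx = keep,
                 k0 = keep - 1L, freq = freq[keep],
                 f_low = f_low, f_high = f_high, fs = fs, n = n),
            class = "doc_band")
}

#' @export
print.doc_band <- function(x, ...) {
  cat(sprintf("<doc_band> %g-%g Hz -> bins L = %d .. H = %d (%d bins)\n",
              x$f_low, x$f_high, x$L, x$H, length(x$idx)))
  invisible(x)
}

band_power <- function(p, band) {
  stopifnot(inherits(p, "doc_spectrum"), inherits(band, "doc_band"))
  if (band$n != p$n || band$fs != p$fs) {
    abort("band was built for a different fs or DFT length")
  }
  p$power[band$idx]
}

#' Normalize a spectrum over a band
#'
#' Rescales the retained in-band powers so they sum to one, turning the power
#' spectrum into a probability distribution over bins (the substrate of
#' spectral entropy).
#'
#' @param p A `doc_spectrum`.
#' @param band A `doc_band` from [band_indices()].
#'
#' @return A `doc_spectrum` whose `power` holds only the in-band bins
#'   (summing to 1) and carries `band` and `normalized = TRUE`.
#' @export
normalize_spectrum <- function(p, band) {
  if (isTRUE(p$normalized)) {
    if (!identical(p$band$idx, band$idx)) {
      abort("spectrum already normalized over a different band")
    }
    return(p) # idempotent
  }
  pw <- band_power(p, band)
  s <- sum(pw)
  if (s <= 0) abort("degenerate spectrum: all in-band power is zero")
  structure(list(power = pw / s, fs = p$fs, n = p$n, normalized = TRUE,
                 window = p$window, band = band),
            class = "doc_spectrum")
}
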
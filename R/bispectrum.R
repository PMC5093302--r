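#' Bispectrum magnitude over a band
#'
#' Averaged triple product of spectral components over sub-epochs:
#' `B(f_i, f_j) = |sum_l X_l(f_i) X_l(f_j) X_l*(f_i + f_j)|` for in-band
#' pairs with `f_i <= f_j` and `f_i + f_j` below Nyquist. Phase-coupled
#' triplets accumulate coherently across sub-epochs, so B grows with the
#' number of sub-epochs at coupled pairs and stays near zero elsewhere.
#'
#' @param epochs A list of equal-length sub-epochs (`doc_epoch`s or numeric
#'   vectors), at least two.
#' @param band A `doc_band` built for the sub-epoch length.
#' @param fs Sampling rate, required when sub-epochs are bare vectors.
#' @param window Taper applied to each sub-epoch before the DFT.
#'
#' @return A `doc_bispec`: list with `magnitude` (square matrix over band
#'   bins, `NA` off the valid triangular grid), `freq` (bin frequencies),
#'   `band`, `n_subepochs`.
#' @export
bispectrum <- function(epochs, band, fs = NULL,
                       window = c("blackman", "rectangular")) {
  window <- match.arg(window)
  if (length(epochs) < 2) abort("need at least 2 sub-epochs")
  if (inherits(epochs[[1]], "doc_epoch")) fs <- epochs[[1]]$fs
  if (is.null(fs)) abort("`fs` required when sub-epochs are bare vectors")
  xs <- lapply(epochs, epoch_samples)
  n <- length(xs[[1]])
  if (any(vapply(xs, length, integer(1)) != n)) {
    abort("all sub-epochs must have the same length")
  }
  if (band$n != n || band$fs != fs) {
    abort("band was built for a different fs or DFT length")
  }
  w <- switch(window, blackman = blackman_window(n), rectangular = rep(1, n))
  k0 <- band$k0
  nb <- length(k0)
  sum_idx <- outer(k0, k0, "+") # 0-based bin of f_i + f_j
  valid <- outer(seq_len(nb), seq_len(nb), "<=") & (sum_idx <= n / 2)
  acc <- matrix(0 + 0i, nb, nb)
  for (x in xs) {
    X <- fft(w * x)
    acc <- acc + outer(X[band$idx], X[band$idx]) *
      Conj(X[(sum_idx %% n) + 1L])
  }
  mag <- Mod(acc)
  mag[!valid] <- NA_real_
  structure(list(magnitude = mag, freq = band$freq, band = band,
                 n_subepochs = length(xs)),
            class = "doc_bispec")
}

#' @export
print.doc_bispec <- function(x, ...) {
  cat(sprintf("<doc_bispec> %d x %d grid (%g-%g Hz), %d sub-epochs\n",
              nrow(x$magnitude), ncol(x$magnitude),
              x$band$f_low, x$band$f_high, x$n_subepochs))
  invisible(x)
}

#' SynchFastSlow (SFS)
#'
#' Natural log of the ratio of summed bispectral magnitudes over the full
#' 0.5-47 Hz band to those over the 40-47 Hz band; the 40-47 Hz grid is the
#' subset of the full grid whose pair frequencies both lie in 40-47 Hz.
#' Rising delta-band phase coupling under anesthesia inflates the numerator,
#' so SFS increases with hypnotic depth.
#'
#' @param epochs A list of equal-length sub-epochs (for the default
#'   pipeline, 2 s windows with 50% overlap tiled across a 10 s epoch).
#' @param fs Sampling rate, required when sub-epochs are bare vectors.
#' @param band_full,band_gamma Numerator and denominator bands in Hz.
#' @param window Sub-epoch taper.
#'
#' @return A scalar (natural-log units); `+Inf` with a warning when the
#'   denominator grid holds no power.
#' @export
synch_fast_slow <- function(epochs, fs = NULL,
                            band_full = c(0.5, 47),
                            band_gamma = c(40, 47),
                            window = c("blackman", "rectangular")) {
  window <- match.arg(window)
  if (inherits(epochs[[1]], "doc_epoch")) fs <- epochs[[1]]$fs
  if (is.null(fs)) abort("`fs` required when sub-epochs are bare vectors")
  n <- length(epoch_samples(epochs[[1]]))
  band <- band_indices(fs, n, band_full[1], band_full[2])
  bsp <- bispectrum(epochs, band, fs = fs, window = window)
  in_gamma <- bsp$freq >= band_gamma[1] & bsp$freq <= band_gamma[2]
  num <- sum(bsp$magnitude, na.rm = TRUE)
  den <- sum(bsp$magnitude[in_gamma, in_gamma], na.rm = TRUE)
  if (den <= 0) {
    warn("zero bispectral power in the gamma band; SFS is +Inf")
    return(Inf)
  }
  log(num / den)
}

# Tile sub-epochs (length subepoch_s, given fractional overlap) from one
# analysis epoch; used by the pipeline's SFS evaluation.
subepochs_of <- function(e, subepoch_s = 2, overlap = 0.5) {
  x <- epoch_samples(e)
  fs <- if (inherits(e, "doc_epoch")) e$fs else abort("need a doc_epoch")
  n_sub <- round(subepoch_s * fs)
  step <- max(1L, round(n_sub * (1 - overlap)))
  starts <- seq(1L, length(x) - n_sub + 1L, by = step)
  lapply(starts, function(s) {
    structure(list(samples = x[s:(s + n_sub - 1L)], fs = fs,
                   start_time = NA_real_, length = subepoch_s),
              class = "doc_epoch")
  })
}
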
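#' Spectral entropy (SpE)
#'
#' Shannon entropy of the normalized in-band power spectrum, divided by
#' `log(H - L + 1)` so that a single spectral component gives 0 and a flat
#' in-band spectrum gives 1. The `0 * log(1/0)` terms are taken as 0.
#'
#' @param p A `doc_spectrum` (normalized internally over `band` if raw).
#' @param band A `doc_band`; must contain at least two bins.
#'
#' @return A scalar in `[0, 1]`.
#' @export
spectral_entropy <- function(p, band) {
  if (!isTRUE(p$normalized)) p <- normalize_spectrum(p, band)
  pr <- p$power
  if (length(pr) < 2) abort("band must contain at least two bins")
  pos <- pr > 0
  max(0, -sum(pr[pos] * log(pr[pos])) / log(length(pr)))
}

# All permutations of 1..m, one per row (lexicographic).
perm_table <- function(m) {
  if (m == 1) return(matrix(1L, 1, 1))
  sub <- perm_table(m - 1L)
  out <- NULL
  for (k in seq_len(m)) {
    block <- cbind(k, ifelse(sub >= k, sub + 1L, sub))
    out <- rbind(out, block)
  }
  unname(out)
}

#' Ordinal pattern distribution
#'
#' Counts, over all admissible start indices, the rank-order pattern of
#' `m` samples taken `tau` apart (the standard `m`-point embedding spanning
#' `(m - 1) * tau` samples; `embedding = "extended"` uses `m + 1` points
#' spanning `m * tau`). Ties are broken by order of occurrence (a stable
#' ranking), so equal samples count as ascending.
#'
#' @param x A `doc_epoch` or numeric vector.
#' @param m Embedding dimension (number of ranked samples with the standard
#'   embedding).
#' @param tau Lag between samples, in samples.
#' @param embedding `"standard"` (default) or `"extended"`.
#'
#' @return A `doc_ordinal`: list with `m`, `tau`, `counts` (length
#'   `m_pts!` with `m_pts` the ranked-vector length), `probs`, and
#'   `patterns` (the rank vectors, one per row).
#' @examples
#' ordinal_distribution(c(3, 1, 2), m = 3, tau = 1)$probs
#' @export
ordinal_distribution <- function(x, m, tau = 1,
                                 embedding = c("standard", "extended")) {
  embedding <- match.arg(embedding)
  x <- epoch_samples(x)
  m_pts <- if (embedding == "standard") m else m + 1L
  span <- (m_pts - 1L) * tau
  n <- length(x)
  if (n < span + 1L) abort("series too short for this (m, tau)")
  n_vec <- n - span
  # columns of the embedded matrix: x[i], x[i + tau], ..., i = 1..n_vec
  emb <- vapply(0:(m_pts - 1L), function(j) x[(1 + j * tau):(n_vec + j * tau)],
                numeric(n_vec))
  if (n_vec == 1L) emb <- matrix(emb, nrow = 1L)
  # stable ranks: r_k = 1 + #{l : x_l < x_k} + #{l < k : x_l == x_k}
  r <- matrix(1L, n_vec, m_pts)
  for (k in seq_len(m_pts)) {
    for (l in seq_len(m_pts)) {
      if (l == k) next
      lt <- emb[, l] < emb[, k]
      if (l < k) lt <- lt | (emb[, l] == emb[, k])
      r[, k] <- r[, k] + lt
    }
  }
  code <- as.vector((r - 1L) %*% m_pts^(0:(m_pts - 1L)))
  pats <- perm_table(m_pts)
  pat_code <- as.vector((pats - 1L) %*% m_pts^(0:(m_pts - 1L)))
  counts <- tabulate(match(code, pat_code), nbins = nrow(pats))
  structure(list(m = m, tau = tau, embedding = embedding,
                 counts = counts, probs = counts / sum(counts),
                 patterns = pats),
            class = "doc_ordinal")
}

shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Permutation entropy (PE)
#'
#' Sum of the ordinal-pattern Shannon entropies at lags `tau = 1` and
#' `tau = 2` (capturing fast and slow oscillations), normalized to lie in
#' `[0, 1]`. The default normalization divides by `2 * log(m!)` (each lag's
#' entropy is at most `log(m!)`); `normalization = "log_mp1fact_half"`
#' divides by `log((m + 1)! / 2)` instead, an alternative reading of the
#' source normalizer that does not guarantee boundedness.
#'
#' @param x A `doc_epoch` or numeric vector.
#' @param m Embedding dimension (default 3).
#' @param taus Lags to sum over (default `c(1, 2)`).
#' @param normalization `"two_log_mfact"` (default) or `"log_mp1fact_half"`.
#' @param embedding Passed to [ordinal_distribution()].
#'
#' @return A scalar (in `[0, 1]` under the default normalization).
#' @export
permutation_entropy <- function(x, m = 3, taus = c(1, 2),
                                normalization = c("two_log_mfact",
                                                  "log_mp1fact_half"),
                                embedding = c("standard", "extended")) {
  normalization <- match.arg(normalization)
  embedding <- match.arg(embedding)
  x <- epoch_samples(x)
  h <- sum(vapply(taus, function(tau) {
    shannon(ordinal_distribution(x, m, tau, embedding)$probs)
  }, numeric(1)))
  m_pts <- if (embedding == "standard") m else m + 1L
  z <- switch(normalization,
              two_log_mfact = length(taus) * log(factorial(m_pts)),
              log_mp1fact_half = log(factorial(m + 1) / 2))
  h / z
}

#' Approximate entropy (AE)
#'
#' Classic approximate entropy: `AE = phi_m(r) - phi_(m+1)(r)` with
#' `phi_m(r)` the mean log fraction of template vectors within Chebyshev
#' distance `r` (self-matches included). The tolerance is
#' `r_factor * SD` of the analyzed samples; analysis uses the final
#' `n_samples` samples of the epoch (the most recent data), defaulting to
#' 1024 samples (4 s at 256 Hz).
#'
#' @param x A `doc_epoch` or numeric vector.
#' @param m Embedding dimension (default 2).
#' @param r_factor Tolerance as a fraction of the SD (default 0.2).
#' @param n_samples Number of trailing samples analyzed (default 1024); the
#'   epoch must be at least this long.
#'
#' @return A nonnegative scalar; 0 for a constant series by convention.
#' @export
approximate_entropy <- function(x, m = 2, r_factor = 0.2, n_samples = 1024) {
  x <- epoch_samples(x)
  if (length(x) < n_samples) {
    abort("epoch shorter than `n_samples`")
  }
  x <- tail(x, n_samples)
  s <- sd(x)
  if (s == 0) return(0)
  apen_cpp(x, as.integer(m), r_factor * s)
}
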
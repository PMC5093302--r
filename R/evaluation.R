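#' Somers' D
#'
#' Asymmetric rank association `D_{Y|X} = (concordant - discordant) /
#' (pairs untied on X)`, with the EEG index as the dependent variable `y`
#' and the effect-site concentration as the independent variable `x`.
#' Computed by direct pair enumeration.
#'
#' @param y_dep Dependent values (index).
#' @param x_indep Independent values (concentration); at least one untied
#'   pair required.
#'
#' @return A scalar in `[-1, 1]`.
#' @examples
#' somers_d(1:5, 1:5) # 1
#' @export
somers_d <- function(y_dep, x_indep) {
  if (length(y_dep) != length(x_indep)) abort("lengths differ")
  if (length(y_dep) < 2) abort("need at least 2 observations")
  sx <- sign(outer(x_indep, x_indep, "-"))
  sy <- sign(outer(y_dep, y_dep, "-"))
  untied_x <- sum(sx != 0) / 2
  if (untied_x == 0) abort("all x values tied; Somers' D undefined")
  cd <- sum(sx * sy) / 2 # concordant - discordant
  cd / untied_x
}

#' Prediction probability (Pk)
#'
#' The probability that an indicator correctly ranks two randomly chosen
#' anesthetic states: `Pk = 1 - (1 - |D|) / 2` with `D` Somers' D of the
#' index on concentration. 1 for a perfect monotone indicator, 0.5 at
#' chance. The standard error is `se(D) / 2`, with `se(D)` estimated by a
#' seeded nonparametric bootstrap.
#'
#' @inheritParams somers_d
#' @param n_boot Bootstrap resamples for the SE (default 1000; 0 skips it).
#' @param seed Seed for the bootstrap resampling (default 1).
#'
#' @return A tibble with `pk`, `somers_d`, `se`, `n`.
#' @export
prediction_probability <- function(y_dep, x_indep, n_boot = 1000, seed = 1) {
  d <- somers_d(y_dep, x_indep)
  se <- NA_real_
  if (n_boot > 0) {
    n <- length(y_dep)
    ds <- withr::with_seed(seed, vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(somers_d(y_dep[idx], x_indep[idx]),
               error = function(e) NA_real_)
    }, numeric(1)))
    se <- sd(ds, na.rm = TRUE) / 2
  }
  tibble::tibble(pk = 1 - (1 - abs(d)) / 2, somers_d = d, se = se,
                 n = length(y_dep))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties).
#'
#' @param y,x Equal-length numeric vectors, `n >= 3`.
#' @return A scalar in `[-1, 1]`.
#' @export
spearman_rho <- function(y, x) {
  if (length(y) != length(x)) abort("lengths differ")
  if (length(y) < 3) abort("need at least 3 observations")
  ry <- rank(y); rx <- rank(x)
  if (var(ry) == 0 || var(rx) == 0) {
    abort("zero rank variance; correlation undefined")
  }
  sum((ry - mean(ry)) * (rx - mean(rx))) /
    sqrt(sum((ry - mean(ry))^2) * sum((rx - mean(rx))^2))
}

#' SpE / SpG sensitivity to amplifying one spectral component
#'
#' Starting from the uniform normalized spectrum `x_i = 1/N`, one component
#' is multiplied by `A` and the spectrum renormalized. Closed forms:
#' normalized spectral entropy
#' `SpE(A) = (log S - (log(1/N) + ((A - 1) log(1/N) + A log A) / N) / S)
#'  / log N` with `S = 1 + (A - 1)/N`, and spectral Gini
#' `SpG(A) = (N - 1) |A - 1| / (N (N + A - 1))`. At `A = 1` these are the
#' unperturbed values 1 and 0. SpG responds to the perturbation more
#' proportionally than SpE, which saturates.
#'
#' @param N Spectrum size (number of bins), `>= 2`.
#' @param A_grid Amplification factors, positive.
#'
#' @return A tibble with columns `N`, `A`, `spe`, `spg`.
#' @examples
#' sensitivity_curves(8, c(1, 2, 10))
#' @export
sensitivity_curves <- function(N, A_grid) {
  if (N < 2) abort("`N` must be >= 2")
  if (any(A_grid <= 0)) abort("amplification factors must be positive")
  xa <- 1 / N
  spe <- vapply(A_grid, function(A) {
    S <- 1 + (A - 1) * xa
    # -sum x'_i log x'_i with x'_i = x_i/S (i != a), x'_a = A x_a / S
    h <- log(S) - (log(xa) + (A - 1) * xa * log(xa) + A * xa * log(A)) / S
    h / log(N)
  }, numeric(1))
  spg <- vapply(A_grid, function(A) {
    (N - 1) * abs(A - 1) / (N * (N + A - 1))
  }, numeric(1))
  tibble::tibble(N = N, A = A_grid, spe = spe, spg = spg)
}

#' Plot SpE / SpG sensitivity curves
#'
#' @param N_values Spectrum sizes, one curve per size.
#' @param A_grid Amplification factors.
#' @return A ggplot comparing the two indices' response to amplification.
#' @export
plot_sensitivity <- function(N_values = c(4, 8, 16, 32, 64),
                             A_grid = exp(seq(log(0.1), log(100),
                                              length.out = 200))) {
  curves <- purrr::map_dfr(N_values, sensitivity_curves, A_grid = A_grid)
  long <- tidyr::pivot_longer(curves, c("spe", "spg"),
                              names_to = "index", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$A, y = .data$value,
                                     colour = factor(.data$N))) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~ toupper(index), scales = "free_y") +
    ggplot2::labs(x = "amplification A", y = "index value",
                  colour = "N") +
    ggplot2::theme_minimal()
}
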
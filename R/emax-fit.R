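#' Fit a sigmoid Emax model to index observations
#'
#' Nonlinear least squares (additive error) of
#' `E = E0 + (Emax - E0) Ce^gamma / (Ce50^gamma + Ce^gamma)` against
#' observed index values at known effect-site concentrations. Starting
#' values come from the data (low-/high-concentration means and the
#' mid-effect concentration) unless supplied.
#'
#' @param data A data frame with columns `ce` and `e` (or vectors via
#'   `ce`/`e` arguments).
#' @param ce,e Alternative vector interface.
#' @param start Optional named list of starting values
#'   (`E0`, `Emax`, `Ce50`, `gamma`).
#'
#' @return An `emax_fit`: list with `params` (E0, Emax, Ce50, gamma),
#'   `sigma` (residual SD), `fitted`, `residuals`, `data`, `nls` (the
#'   underlying fit), and `ke0 = NA`. Supports [tidy()], [glance()],
#'   [autoplot()].
#' @examples
#' pd <- list(E0 = 0.04, Emax = 0.37, Ce50 = 2.9, gamma = 3.9)
#' ce <- seq(0, 8, length.out = 60)
#' fit <- fit_emax(ce = ce, e = emax_effect(ce, pd))
#' tidy(fit)
#' @export
fit_emax <- function(data = NULL, ce = NULL, e = NULL, start = NULL) {
  if (!is.null(data)) {
    ce <- data$ce
    e <- data$e
  }
  if (length(ce) != length(e)) abort("`ce` and `e` lengths differ")
  keep <- is.finite(ce) & is.finite(e)
  ce <- ce[keep]; e <- e[keep]
  if (length(ce) < 10) abort("need at least 10 observations")
  if (is.null(start)) start <- emax_start_values(ce, e)
  df <- data.frame(ce = ce, e = e)
  fit <- minpack.lm::nlsLM(
    e ~ E0 + (Emax - E0) * ce^gamma / (Ce50^gamma + ce^gamma),
    data = df, start = start,
    lower = c(E0 = -Inf, Emax = -Inf, Ce50 = 1e-6, gamma = 1e-3),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  params <- as.list(coef(fit))
  structure(list(params = params,
                 sigma = sqrt(sum(resid(fit)^2) /
                                max(1, length(ce) - 4)),
                 fitted = fitted(fit), residuals = resid(fit),
                 data = tibble::as_tibble(df), nls = fit, ke0 = NA_real_),
            class = "emax_fit")
}

emax_start_values <- function(ce, e) {
  qs <- quantile(ce, c(0.1, 0.9))
  e0 <- mean(e[ce <= qs[1]])
  emax <- mean(e[ce >= qs[2]])
  if (!is.finite(e0)) e0 <- e[which.min(ce)]
  if (!is.finite(emax)) emax <- e[which.max(ce)]
  mid <- (e0 + emax) / 2
  ce50 <- ce[which.min(abs(e - mid))]
  if (!is.finite(ce50) || ce50 <= 0) ce50 <- stats::median(ce[ce > 0])
  list(E0 = e0, Emax = emax, Ce50 = ce50, gamma = 2)
}

#' Fit a sigmoid Emax model jointly with the effect-site rate constant
#'
#' When only plasma concentrations are known, `ke0` is estimated along with
#' the Emax parameters: the profile residual sum of squares over a
#' log-spaced `ke0` grid (default 0.01-1 /min, 50 points) is minimized,
#' then refined by golden-section search between the neighbouring grid
#' points; at each candidate `ke0` the effect-site course is computed by
#' [effect_site()] and the conditional Emax fit by [fit_emax()].
#'
#' @param conc A tibble with `time_min` and `cp` covering the observation
#'   times.
#' @param data A data frame of observations with columns `time_min` and `e`.
#' @param ke0_grid Candidate `ke0` values for the profile search.
#'
#' @return An `emax_fit` whose `params` include `ke0`.
#' @export
fit_emax_with_ke0 <- function(conc, data,
                              ke0_grid = exp(seq(log(0.01), log(1),
                                                 length.out = 50))) {
  if (!all(c("time_min", "e") %in% names(data))) {
    abort("`data` needs columns time_min, e")
  }
  rss_at <- function(ke0) {
    ce_full <- effect_site(conc[, c("time_min", "cp")], ke0)
    ce_obs <- approx(ce_full$time_min, ce_full$ce, xout = data$time_min,
                     rule = 2)$y
    fit <- try(fit_emax(ce = ce_obs, e = data$e), silent = TRUE)
    if (inherits(fit, "try-error")) return(list(rss = Inf, fit = NULL))
    list(rss = sum(fit$residuals^2), fit = fit, ce = ce_obs)
  }
  prof <- lapply(ke0_grid, rss_at)
  rss <- vapply(prof, `[[`, numeric(1), "rss")
  if (!any(is.finite(rss))) {
    abort("sigmoid Emax fit failed at every ke0 candidate")
  }
  i <- which.min(rss)
  lo <- ke0_grid[max(1, i - 1)]
  hi <- ke0_grid[min(length(ke0_grid), i + 1)]
  opt <- stats::optimize(function(k) rss_at(k)$rss, c(lo, hi))
  best_k <- if (opt$objective < rss[i]) opt$minimum else ke0_grid[i]
  best <- rss_at(best_k)
  out <- best$fit
  out$params$ke0 <- best_k
  out$ke0 <- best_k
  out$data$time_min <- data$time_min
  out
}

#' @export
print.emax_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<emax_fit> E0 = %.4g, Emax = %.4g, Ce50 = %.4g, gamma = %.4g%s (sigma = %.3g, n = %d)\n",
    p$E0, p$Emax, p$Ce50, p$gamma,
    if (is.finite(x$ke0)) sprintf(", ke0 = %.4g", x$ke0) else "",
    x$sigma, nrow(x$data)))
  invisible(x)
}

#' @rdname fit_emax
#' @param x An `emax_fit`.
#' @param ... Unused.
#' @export
tidy.emax_fit <- function(x, ...) {
  est <- unlist(x$params)
  se <- rep(NA_real_, length(est))
  nls_se <- tryCatch(summary(x$nls)$coefficients[, "Std. Error"],
                     error = function(e) NULL)
  if (!is.null(nls_se)) se[match(names(nls_se), names(est))] <- nls_se
  tibble::tibble(term = names(est), estimate = unname(est),
                 std.error = se)
}

#' @rdname fit_emax
#' @export
glance.emax_fit <- function(x, ...) {
  tibble::tibble(sigma = x$sigma,
                 rss = sum(x$residuals^2),
                 nobs = nrow(x$data),
                 ke0 = x$ke0)
}

#' @rdname fit_emax
#' @param object An `emax_fit`.
#' @export
autoplot.emax_fit <- function(object, ...) {
  grid <- tibble::tibble(
    ce = seq(0, max(object$data$ce) * 1.05, length.out = 200))
  grid$e <- emax_effect(grid$ce, object$params)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$ce, y = .data$e)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(x = "effect-site concentration (ug/mL)",
                  y = "index value",
                  title = "Sigmoid Emax fit") +
    ggplot2::theme_minimal()
}
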
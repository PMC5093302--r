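#' Covariate pharmacokinetic parameters for propofol
#'
#' Builds the three-compartment disposition parameters from the subject
#' covariates: central volume `V1 = theta1 + (LBM / 45)^theta2` (lean body
#' mass, kg) and metabolic clearance `Cl = theta3 + (WT / weight_ref)^theta4`
#' (total body weight, kg). Remaining parameters are the population point
#' estimates: `V2 = 75.3 L`, `V3 = 846 L`, `Q1 = 0.928 L/min`,
#' `Q2 = 0.679 L/min`. The published model reports the weight scaling
#' reference inconsistently (58 vs 63 kg); both are supported via
#' `weight_ref`, defaulting to 58 (the final-model table).
#'
#' @param LBM Lean body mass, kg.
#' @param WT Total body weight, kg.
#' @param theta Named numeric vector of structural parameters; defaults to
#'   the population estimates `theta1 = 10.3`, `theta2 = 6.63`,
#'   `theta3 = 0.217`, `theta4 = 1.02`, `V2 = 75.3`, `V3 = 846`,
#'   `Q1 = 0.928`, `Q2 = 0.679`.
#' @param weight_ref Clearance weight scaling reference, kg (default 58).
#'
#' @return A `pk_params`: list with `V1`, `V2`, `V3` (L) and `Cl`, `Q1`,
#'   `Q2` (L/min), plus the covariates used.
#' @examples
#' covariate_pk(LBM = 45, WT = 63, weight_ref = 63)$V1 # 11.3
#' @export
covariate_pk <- function(LBM, WT,
                         theta = c(theta1 = 10.3, theta2 = 6.63,
                                   theta3 = 0.217, theta4 = 1.02,
                                   V2 = 75.3, V3 = 846,
                                   Q1 = 0.928, Q2 = 0.679),
                         weight_ref = 58) {
  if (LBM <= 0 || WT <= 0) abort("covariates must be positive")
  structure(list(
    V1 = unname(theta["theta1"] + (LBM / 45)^theta["theta2"]),
    V2 = unname(theta["V2"]),
    V3 = unname(theta["V3"]),
    Cl = unname(theta["theta3"] + (WT / weight_ref)^theta["theta4"]),
    Q1 = unname(theta["Q1"]),
    Q2 = unname(theta["Q2"]),
    LBM = LBM, WT = WT, weight_ref = weight_ref
  ), class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat(sprintf(
    "<pk_params> V1 = %.3g, V2 = %.3g, V3 = %.3g L; Cl = %.3g, Q1 = %.3g, Q2 = %.3g L/min\n",
    x$V1, x$V2, x$V3, x$Cl, x$Q1, x$Q2))
  invisible(x)
}

#' Infusion regimen
#'
#' Zero-order intravenous infusion into the central compartment. The
#' reference regimen is 12 mg/kg/h for 60 min.
#'
#' @param rate Infusion rate, mg/kg/h.
#' @param duration Infusion duration, min.
#' @param weight Body weight, kg.
#' @param start Infusion start, min (default 0).
#'
#' @return An `infusion_regimen` list; `rate_mg_min` holds the absolute
#'   zero-order rate in mg/min.
#' @export
infusion_regimen <- function(rate = 12, duration = 60, weight = 70,
                             start = 0) {
  if (rate < 0) abort("`rate` must be nonnegative")
  if (duration <= 0) abort("`duration` must be positive")
  structure(list(rate = rate, duration = duration, weight = weight,
                 start = start,
                 rate_mg_min = rate * weight / 60),
            class = "infusion_regimen")
}

# Rate matrix of the mammillary three-compartment model, in amounts (mg).
pk_rate_matrix <- function(pk) {
  k10 <- pk$Cl / pk$V1
  k12 <- pk$Q1 / pk$V1; k21 <- pk$Q1 / pk$V2
  k13 <- pk$Q2 / pk$V1; k31 <- pk$Q2 / pk$V3
  matrix(c(-(k10 + k12 + k13), k21, k31,
           k12, -k21, 0,
           k13, 0, -k31),
         nrow = 3, byrow = TRUE)
}

# Advance the linear system dA/dt = K A + b over dt (vectorized over dt),
# via the eigendecomposition of K; phi(z) = (exp(z) - 1) / z handles zero
# eigenvalues (e.g. closed peripheral compartments).
pk_advance <- function(K, A0, b, dt) {
  eg <- eigen(K)
  P <- eg$vectors
  Pi <- solve(P)
  lam <- eg$values
  a0 <- Pi %*% A0
  bb <- Pi %*% b
  phi <- function(z) ifelse(abs(z) < 1e-12, 1, (exp(z) - 1) / z)
  out <- vapply(dt, function(h) {
    y <- exp(lam * h) * a0 + h * phi(lam * h) * bb
    Re(P %*% y)[, 1]
  }, numeric(nrow(K)))
  t(out) # rows = times, cols = compartments
}

#' Simulate plasma concentration (three-compartment model)
#'
#' Solves the mammillary three-compartment disposition model (central
#' elimination `Cl`, intercompartmental clearances `Q1`, `Q2`) under a
#' zero-order infusion, piecewise-analytically via the eigendecomposition of
#' the linear system — exact to machine precision on each constant-rate
#' interval. Plasma concentration is the central amount over `V1`;
#' mg and L give mg/L, i.e. ug/mL.
#'
#' @param reg An [infusion_regimen()].
#' @param pk A [covariate_pk()] result (or compatible list).
#' @param grid Time grid in minutes, sorted, starting at or before the
#'   infusion start.
#'
#' @return A tibble with `time_min`, `cp` (ug/mL), the three compartment
#'   amounts `a1`, `a2`, `a3` (mg), and the cumulative `eliminated` mass
#'   (mg), integrated as a fourth state so mass balance holds to solver
#'   precision.
#' @export
simulate_pk <- function(reg, pk, grid) {
  if (is.unsorted(grid)) abort("`grid` must be sorted")
  if (grid[1] > reg$start) abort("grid must start at or before the infusion")
  K3 <- pk_rate_matrix(pk)
  # fourth state: cumulative eliminated mass, dE/dt = k10 * a1
  K <- rbind(cbind(K3, 0), c(pk$Cl / pk$V1, 0, 0, 0))
  t_on <- reg$start
  t_off <- reg$start + reg$duration
  b_on <- c(reg$rate_mg_min, 0, 0, 0)
  b_off <- c(0, 0, 0, 0)
  A <- matrix(0, length(grid), 4)
  # segment boundaries: [grid start, t_on), [t_on, t_off), [t_off, end]
  seg_starts <- c(grid[1], t_on, t_off)
  seg_inputs <- list(b_off, b_on, b_off)
  A0 <- c(0, 0, 0, 0)
  for (s in seq_along(seg_starts)) {
    s0 <- seg_starts[s]
    s1 <- if (s < length(seg_starts)) seg_starts[s + 1] else Inf
    sel <- which(grid >= s0 & grid < s1)
    if (s == length(seg_starts)) sel <- which(grid >= s0)
    if (length(sel)) {
      A[sel, ] <- pk_advance(K, A0, seg_inputs[[s]], grid[sel] - s0)
    }
    if (is.finite(s1) && s1 > s0) {
      A0 <- as.numeric(pk_advance(K, A0, seg_inputs[[s]], s1 - s0))
    }
  }
  tibble::tibble(time_min = grid, cp = A[, 1] / pk$V1,
                 a1 = A[, 1], a2 = A[, 2], a3 = A[, 3],
                 eliminated = A[, 4])
}

#' Effect-site concentration
#'
#' First-order link `dCe/dt = ke0 (Cp - Ce)`, `Ce(0) = 0`, integrated
#' exactly on the grid assuming `Cp` varies linearly (default) or is
#' constant (`interp = "constant"`, left-continuous) between grid points.
#'
#' @param conc A tibble with `time_min` and `cp` (from [simulate_pk()]), or
#'   a numeric vector of plasma concentrations with `times` supplied.
#' @param ke0 Plasma/effect-site equilibration rate constant, 1/min.
#' @param times Time grid (min) when `conc` is a bare vector.
#' @param interp `"linear"` or `"constant"` inter-sample behaviour of Cp.
#'
#' @return The input tibble with a `ce` column appended (or a numeric vector
#'   of Ce when `conc` was a vector).
#' @export
effect_site <- function(conc, ke0, times = NULL,
                        interp = c("linear", "constant")) {
  interp <- match.arg(interp)
  if (ke0 <= 0) abort("`ke0` must be positive")
  bare <- !is.data.frame(conc)
  if (bare) {
    cp <- as.numeric(conc)
    if (is.null(times)) abort("`times` required for a bare Cp vector")
  } else {
    cp <- conc$cp
    times <- conc$time_min
  }
  n <- length(cp)
  ce <- numeric(n)
  for (i in seq_len(n - 1)) {
    h <- times[i + 1] - times[i]
    c0 <- cp[i]
    slope <- if (interp == "linear") (cp[i + 1] - cp[i]) / h else 0
    # exact solution over the step for Cp(s) = c0 + slope * s
    ce[i + 1] <- c0 + slope * h - slope / ke0 +
      (ce[i] - c0 + slope / ke0) * exp(-ke0 * h)
  }
  if (bare) ce else dplyr::mutate(conc, ce = ce)
}

#' Simulate a full concentration course
#'
#' Convenience wrapper: [simulate_pk()] then [effect_site()].
#'
#' @inheritParams simulate_pk
#' @inheritParams effect_site
#' @return A tibble with `time_min`, `cp`, `ce`.
#' @export
pk_concentration_series <- function(reg, pk, ke0, grid) {
  conc <- simulate_pk(reg, pk, grid)
  effect_site(conc[, c("time_min", "cp")], ke0)
}

#' Sigmoid Emax concentration-effect model
#'
#' `E = E0 + (Emax - E0) * Ce^gamma / (Ce50^gamma + Ce^gamma)`: baseline
#' `E0` with no drug, asymptote `Emax`, half-effect concentration `Ce50`,
#' steepness `gamma`.
#'
#' @param ce Effect-site concentrations (ug/mL), nonnegative.
#' @param pd Named list/vector with `E0`, `Emax`, `Ce50`, `gamma`.
#'
#' @return Effect values, same length as `ce`.
#' @examples
#' emax_effect(2.88, list(E0 = 0.037, Emax = 0.367, Ce50 = 2.88,
#'                        gamma = 3.85)) # (E0 + Emax) / 2
#' @export
emax_effect <- function(ce, pd) {
  pd <- as.list(pd)
  if (any(ce < 0)) abort("`ce` must be nonnegative")
  cg <- ce^pd$gamma
  pd$E0 + (pd$Emax - pd$E0) * cg / (pd$Ce50^pd$gamma + cg)
}
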
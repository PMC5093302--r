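test_that("covariate model reproduces its unit-base values", {
  expect_equal(covariate_pk(LBM = 45, WT = 70)$V1, 11.3)
  expect_equal(covariate_pk(LBM = 55, WT = 63, weight_ref = 63)$Cl, 1.217)
  # V1 strictly increasing in LBM
  v <- vapply(c(35, 45, 55, 65), function(l) covariate_pk(l, 70)$V1,
              numeric(1))
  expect_true(all(diff(v) > 0))
  expect_error(covariate_pk(-1, 70), "positive")
})

test_that("PK solver collapses to the one-compartment closed form", {
  pk <- list(V1 = 10, V2 = 75, V3 = 846, Cl = 1.2, Q1 = 0, Q2 = 0)
  reg <- infusion_regimen(12, 60, 70)
  grid <- seq(0, 120, by = 0.5)
  sim <- simulate_pk(reg, pk, grid)
  R <- reg$rate_mg_min
  k <- pk$Cl / pk$V1
  cp60 <- (R / pk$Cl) * (1 - exp(-k * 60))
  exact <- ifelse(grid <= 60, (R / pk$Cl) * (1 - exp(-k * grid)),
                  cp60 * exp(-k * (grid - 60)))
  expect_equal(sim$cp, exact, tolerance = 1e-6)
})

test_that("infinite infusion reaches the steady state R / Cl", {
  pk <- covariate_pk(55, 70)
  reg <- infusion_regimen(12, 1e5, 70)
  sim <- simulate_pk(reg, pk, c(0, 1e5))
  expect_equal(sim$cp[2], reg$rate_mg_min / pk$Cl, tolerance = 1e-6)
})

test_that("mass is conserved at every grid point", {
  pk <- covariate_pk(55, 70)
  reg <- infusion_regimen(12, 60, 70)
  grid <- seq(0, 130, by = 0.5)
  sim <- simulate_pk(reg, pk, grid)
  infused <- pmin(grid, 60) * reg$rate_mg_min
  in_body <- sim$a1 + sim$a2 + sim$a3
  expect_true(all(in_body <= infused + 1e-9))
  retained <- infused - sim$eliminated
  expect_equal(in_body[-1], retained[-1],
               tolerance = 1e-6)
})

test_that("matrix-exponential solution matches a generic ODE solver", {
  skip_if_not_installed("deSolve")
  pk <- covariate_pk(55, 70)
  reg <- infusion_regimen(12, 60, 70)
  grid <- seq(0, 130, by = 1)
  sim <- simulate_pk(reg, pk, grid)
  K <- docgini:::pk_rate_matrix(pk)
  rhs <- function(t, A, parms) {
    inp <- if (t < 60) reg$rate_mg_min else 0
    list(as.numeric(K %*% A) + c(inp, 0, 0))
  }
  ode <- deSolve::lsoda(c(0, 0, 0), grid, rhs, NULL, rtol = 1e-10,
                        atol = 1e-10)
  expect_equal(sim$a1, unname(ode[, 2]), tolerance = 1e-6)
  expect_equal(sim$a3, unname(ode[, 4]), tolerance = 1e-6)
})

test_that("effect site follows the first-order step response and lags Cp", {
  t <- seq(0, 100, by = 1)
  ce <- effect_site(rep(2, 101), ke0 = 0.1, times = t, interp = "constant")
  expect_equal(ce, 2 * (1 - exp(-0.1 * t)), tolerance = 1e-12)

  pk <- covariate_pk(55, 70)
  conc <- simulate_pk(infusion_regimen(12, 60, 70), pk, seq(0, 130, 0.25))
  both <- effect_site(conc[, c("time_min", "cp")], ke0 = 0.081)
  expect_gte(both$time_min[which.max(both$ce)],
             both$time_min[which.max(both$cp)])
  # very fast equilibration: Ce tracks Cp
  fast <- effect_site(conc[, c("time_min", "cp")], ke0 = 100)
  expect_lt(max(abs(fast$ce - fast$cp)[-(1:8)]), 0.02 * max(fast$cp))
})

test_that("effect site equals the discrete convolution for step-wise Cp", {
  set.seed(51)
  t <- 0:200
  cp <- rep(rexp(20), length.out = 201)
  ke0 <- 0.3
  ce <- effect_site(cp, ke0, times = t, interp = "constant")
  # independent oracle: exact recursion of the convolution integral for a
  # left-continuous step function
  conv <- numeric(201)
  for (i in 2:201) {
    conv[i] <- conv[i - 1] * exp(-ke0) + cp[i - 1] * (1 - exp(-ke0))
  }
  expect_equal(ce, conv, tolerance = 1e-12)
})

test_that("the sigmoid Emax curve hits its anchor points", {
  pd <- list(E0 = 0.037, Emax = 0.367, Ce50 = 2.88, gamma = 3.85)
  expect_equal(emax_effect(0, pd), pd$E0)
  expect_equal(emax_effect(pd$Ce50, pd), (pd$E0 + pd$Emax) / 2)
  expect_equal(emax_effect(1e9, pd), pd$Emax, tolerance = 1e-6)
})

test_that("noise-free Emax data are recovered to numerical precision", {
  pd <- list(E0 = 0.8, Emax = 0.2, Ce50 = 1.5, gamma = 5)
  ce <- seq(0, 6, length.out = 80)
  fit <- fit_emax(ce = ce, e = emax_effect(ce, pd))
  expect_equal(unlist(fit$params[c("E0", "Emax", "Ce50", "gamma")]),
               unlist(pd), tolerance = 1e-6)
  # permutation of observations changes nothing
  o <- sample(seq_along(ce))
  fit2 <- fit_emax(ce = ce[o], e = emax_effect(ce, pd)[o])
  expect_equal(unlist(fit2$params), unlist(fit$params), tolerance = 1e-8)
})

test_that("emax fits expose tidy, glance and autoplot", {
  pd <- list(E0 = 0.1, Emax = 0.9, Ce50 = 2, gamma = 3)
  ce <- seq(0, 6, length.out = 40)
  set.seed(52)
  fit <- fit_emax(ce = ce, e = emax_effect(ce, pd) + rnorm(40, 0, 0.01))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$term, c("E0", "Emax", "Ce50", "gamma"))
  expect_true(all(is.finite(td$std.error)))
  gl <- glance(fit)
  expect_equal(gl$nobs, 40L)
  expect_s3_class(autoplot(fit), "ggplot")
})
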
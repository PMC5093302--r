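test_that("identical scenarios generate bit-identical subjects", {
  scn <- subject_scenario(seed = 3, pre_min = 1, infusion_min = 3,
                          post_min = 1)
  a <- suppressWarnings(generate_subject(scn)) # too short for LOC/ROC
  b <- suppressWarnings(generate_subject(scn))
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$conc, b$conc)
  c2 <- suppressWarnings(
    generate_subject(subject_scenario(seed = 4, pre_min = 1,
                                      infusion_min = 3, post_min = 1)))
  expect_false(identical(a$recording$samples, c2$recording$samples))
})

test_that("the awake template is realized within 10% per band", {
  scn <- subject_scenario(seed = 7, pre_min = 5, infusion_min = 1,
                          post_min = 1, rate = 0)
  s <- generate_subject(scn, depth = 0)
  eps <- epoch_stream(s$recording, 10, 10)[1:30] # 5 min
  bpm <- docgini:::default_band_power_map()
  for (b in seq_len(nrow(bpm))) {
    bd <- band_indices(256, 2560, bpm$f_low[b], bpm$f_high[b])
    pw <- vapply(eps, function(e) {
      ps <- power_spectrum(e, window = "rectangular")
      2 * sum(ps$power[bd$idx]) / ps$n^2
    }, numeric(1))
    target <- bpm$awake[b] * (bpm$f_high[b] - bpm$f_low[b])
    expect_lt(abs(mean(pw) / target - 1), 0.1)
  }
})

test_that("at full depth the delta band dominates the analysis band", {
  scn <- subject_scenario(seed = 8, pre_min = 2, infusion_min = 2,
                          post_min = 1, rate = 0)
  s <- generate_subject(scn, depth = 1)
  e <- epoch_stream(s$recording, 60, 60)[[1]]
  ps <- power_spectrum(e, window = "rectangular")
  all_band <- band_indices(256, length(e$samples), 0.8, 47)
  delta <- band_indices(256, length(e$samples), 0.8, 3)
  share <- sum(ps$power[delta$idx]) / sum(ps$power[all_band$idx])
  expect_gt(share, 0.6)
})

test_that("LOC and ROC sit where the depth variable crosses one half", {
  s <- generate_subject(subject_scenario(seed = 9))
  expect_true(all(c("t_I", "t_L", "t_T", "t_R") %in% names(s$events)))
  e_at <- setNames(
    approx(s$conc$time_min * 60, s$conc$e, xout = unlist(s$events))$y,
    names(s$events))
  expect_gte(e_at[["t_L"]], 0.5)
  expect_lt(approx(s$conc$time_min * 60, s$conc$e,
                   xout = s$events$t_L - 2)$y, 0.5)
  expect_lt(e_at[["t_R"]], 0.5)
  expect_true(s$events$t_I < s$events$t_L &&
                s$events$t_L < s$events$t_T &&
                s$events$t_T < s$events$t_R)
})

test_that("the generating kinetics are recoverable from the BSpG series", {
  s <- generate_subject(subject_scenario(seed = 2))
  rep <- suppressWarnings(run_full_pipeline(s, indices = "BSpG", n_boot = 0))
  obs <- data.frame(time_min = rep$samples$scheduled_s / 60,
                    e = rep$samples$smoothed_value)
  fit <- fit_emax_with_ke0(s$conc[, c("time_min", "cp")], obs)
  # the kinetic/location parameters of the latent depth link come back;
  # the spectral pathway rescales E0/Emax and steepens gamma, so those
  # reflect the measured index range instead (see the methods vignette)
  expect_lt(abs(fit$params$ke0 - s$truth$ke0) / s$truth$ke0, 0.15)
  expect_lt(abs(fit$params$Ce50 - s$truth$ce50) / s$truth$ce50, 0.15)
  expect_gt(1 - sum(fit$residuals^2) / sum((obs$e - mean(obs$e))^2), 0.95)
})

test_that("spectrum fixtures are deterministic and ordered by concentration", {
  b <- band_indices(256, 1280, 0.8, 47)
  u <- make_spectrum_fixture("uniform")
  expect_equal(spectral_gini(u, b), 0)
  g_conc <- spectral_gini(make_spectrum_fixture("concentrated"), b)
  g_mid <- spectral_gini(make_spectrum_fixture("intermediate"), b)
  expect_gt(g_conc, g_mid)
  expect_gt(g_mid, 0)
  expect_identical(make_spectrum_fixture("concentrated"),
                   make_spectrum_fixture("concentrated"))
})
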
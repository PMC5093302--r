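default_band_power_map <- function() {
  tibble::tibble(
    band = c("delta", "theta", "alpha", "beta", "gamma"),
    f_low = c(0.5, 4, 8, 13, 30),
    f_high = c(3, 7, 12, 30, 47),
    awake = c(16, 10, 18, 3, 1.5),   # uV^2 / Hz
    deep = c(200, 12, 8, 2, 0.006)
  )
}

#' Synthetic anesthesia scenario
#'
#' Describes one simulated propofol anesthesia course: subject covariates,
#' the infusion regimen (reference: 12 mg/kg/h for 60 min, preceded by 5 min
#' of baseline recording and followed by 60 min of recovery), the
#' concentration-to-depth link, and the awake/deep spectral band-power
#' templates.
#'
#' @param seed Integer seed; the generated subject is a pure function of the
#'   scenario including this seed.
#' @param weight,lbm Body weight and lean body mass, kg.
#' @param rate,infusion_min Infusion rate (mg/kg/h) and duration (min).
#' @param pre_min,post_min Baseline minutes before the infusion and recovery
#'   minutes after it.
#' @param fs Sampling rate, Hz.
#' @param ke0 Effect-site equilibration constant, 1/min.
#' @param ce50,gamma Sigmoid parameters mapping effect-site concentration to
#'   the depth variable `e in [0, 1]` (defaults follow the steepest
#'   estimated index response: Ce50 = 2.88 ug/mL, gamma = 3.85).
#' @param band_power_map Tibble of band edges and awake/deep power densities
#'   (uV^2/Hz); see `docgini:::default_band_power_map()`.
#'
#' @return A `subject_scenario` list.
#' @export
subject_scenario <- function(seed = 1, weight = 70, lbm = 55,
                             rate = 12, infusion_min = 60,
                             pre_min = 5, post_min = 60,
                             fs = 256, ke0 = 0.081,
                             ce50 = 2.88, gamma = 3.85,
                             band_power_map = default_band_power_map()) {
  if (pre_min <= 0 || post_min <= 0 || infusion_min <= 0) {
    abort("durations must be positive")
  }
  if (weight <= 0 || lbm <= 0) abort("weights must be positive")
  if (any(band_power_map$awake < 0) || any(band_power_map$deep < 0)) {
    abort("band powers must be nonnegative")
  }
  structure(list(seed = as.integer(seed), weight = weight, lbm = lbm,
                 rate = rate, infusion_min = infusion_min,
                 pre_min = pre_min, post_min = post_min, fs = fs,
                 ke0 = ke0, ce50 = ce50, gamma = gamma,
                 band_power_map = band_power_map),
            class = "subject_scenario")
}

#' Generate a synthetic anesthesia EEG subject
#'
#' Simulates the plasma and effect-site propofol course for the scenario,
#' maps effect-site concentration through a sigmoid to a depth variable
#' `e(t)` in `[0, 1]`, and synthesizes the EEG as a sum of band-limited
#' Gaussian noise components (white noise through zero-phase 4th-order
#' Butterworth band-pass filters, each calibrated so its in-band power
#' matches the template) whose band powers interpolate geometrically between
#' the awake and deep templates as `e(t)` varies. Awake the spectrum is broad
#' with a mild 8-12 Hz concentration; deep, 0.5-3 Hz power rises more than
#' tenfold while 30-47 Hz power sinks. LOC and ROC events are placed where
#' `e(t)` crosses 0.5. Identical scenarios (including the seed) give
#' bit-identical subjects.
#'
#' @param scn A [subject_scenario()].
#' @param depth Optional depth override: a constant in `[0, 1]` replacing
#'   the PK-driven `e(t)` (used to probe the awake/deep templates directly).
#'
#' @return A `doc_subject`: list with `recording` (a [recording()] carrying
#'   the events), `conc` (tibble `time_min`, `cp`, `ce`, `e`), `events`
#'   (named list, seconds), `truth` (the scenario).
#' @examples
#' subj <- generate_subject(subject_scenario(seed = 1, infusion_min = 5,
#'                                           pre_min = 1, post_min = 2))
#' subj$recording
#' @export
generate_subject <- function(scn, depth = NULL) {
  stopifnot(inherits(scn, "subject_scenario"))
  total_min <- scn$pre_min + scn$infusion_min + scn$post_min
  grid <- seq(0, total_min, by = 1 / 60) # 1 s resolution, minutes
  t_I <- scn$pre_min * 60
  t_T <- (scn$pre_min + scn$infusion_min) * 60
  if (scn$rate > 0) {
    reg <- infusion_regimen(scn$rate, scn$infusion_min, scn$weight,
                            start = scn$pre_min)
    pk <- covariate_pk(scn$lbm, scn$weight)
    conc <- pk_concentration_series(reg, pk, scn$ke0, grid)
  } else {
    conc <- tibble::tibble(time_min = grid, cp = 0, ce = 0)
  }
  conc$e <- emax_effect(conc$ce, list(E0 = 0, Emax = 1, Ce50 = scn$ce50,
                                      gamma = scn$gamma))
  if (!is.null(depth)) conc$e <- rep(depth, length(grid))
  events <- list(t_I = t_I, t_T = t_T)
  cross <- diff(conc$e >= 0.5)
  up <- which(cross == 1)
  down <- which(cross == -1)
  if (length(up)) events$t_L <- conc$time_min[up[1] + 1] * 60
  if (length(down)) events$t_R <- conc$time_min[down[1] + 1] * 60
  if (scn$rate > 0 && is.null(depth) &&
      (is.null(events$t_L) || is.null(events$t_R))) {
    warn("depth never crossed 0.5 in both directions; LOC/ROC missing")
  }
  n <- round(total_min * 60 * scn$fs)
  t_s <- (seq_len(n) - 1) / scn$fs
  e_sig <- approx(conc$time_min * 60, conc$e, xout = t_s, rule = 2)$y
  bpm <- scn$band_power_map
  samples <- withr::with_seed(scn$seed, {
    acc <- numeric(n)
    for (b in seq_len(nrow(bpm))) {
      bf <- signal::butter(4, c(bpm$f_low[b], bpm$f_high[b]) / (scn$fs / 2),
                           type = "pass")
      comp <- signal::filtfilt(bf, rnorm(n + 8 * scn$fs))
      comp <- comp[seq(4 * scn$fs + 1, 4 * scn$fs + n)] # drop edge transients
      # calibrate so the *in-band* power equals the template: the zero-phase
      # pass-band (|H|^4 response) keeps only part of the component's
      # variance inside its nominal edges
      fgrid <- seq(0, scn$fs / 2, length.out = 4096)
      h4 <- Mod(signal::freqz(bf, n = fgrid, Fs = scn$fs)$h)^4
      in_band <- fgrid >= bpm$f_low[b] & fgrid <= bpm$f_high[b]
      frac <- sum(h4[in_band]) / sum(h4)
      comp <- comp / (sd(comp) * sqrt(frac))
      width <- bpm$f_high[b] - bpm$f_low[b]
      pow <- bpm$awake[b]^(1 - e_sig) * bpm$deep[b]^e_sig * width
      acc <- acc + comp * sqrt(pow)
    }
    acc
  })
  ev_order <- c("t_I", "t_L", "t_T", "t_R")
  events <- events[ev_order[ev_order %in% names(events)]]
  structure(list(recording = recording(samples, scn$fs, events),
                 conc = conc, events = events, truth = scn),
            class = "doc_subject")
}

#' @export
print.doc_subject <- function(x, ...) {
  cat(sprintf("<doc_subject> seed %d, %.0f min @ %g Hz\n",
              x$truth$seed, duration_s(x$recording) / 60, x$recording$fs))
  print(x$recording)
  invisible(x)
}

#' Deterministic spectrum fixtures
#'
#' Small synthetic power spectra for exercising the inequality indices:
#' `"concentrated"` piles power below 10 Hz (high SpG), `"intermediate"`
#' decays gently (moderate SpG), `"uniform"` is exactly flat (SpG = 0).
#' All three are 5 s spectra at 256 Hz (N = 1280) and are identical across
#' calls.
#'
#' @param kind One of `"concentrated"`, `"intermediate"`, `"uniform"`.
#' @return A `doc_spectrum`.
#' @examples
#' b <- band_indices(256, 1280, 0.8, 47)
#' spectral_gini(make_spectrum_fixture("uniform"), b) # 0
#' @export
make_spectrum_fixture <- function(kind = c("concentrated", "intermediate",
                                           "uniform")) {
  kind <- match.arg(kind)
  fs <- 256; n <- 1280L
  freq <- (0:(n - 1)) * fs / n
  fold <- pmin(freq, fs - freq) # two-sided symmetry
  prof <- switch(kind,
                 concentrated = exp(-fold / 2.5),
                 intermediate = 1 / (1 + (fold / 10)^2),
                 uniform = rep(1, n))
  structure(list(power = prof, fs = fs, n = n, normalized = FALSE,
                 window = "rectangular"),
            class = "doc_spectrum")
}
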
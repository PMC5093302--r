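index_names <- c("SpE", "PE", "AE", "DFA", "SFS", "SpG", "BSpG")

# Evaluate one index on one epoch. `ctx` carries precomputed pieces shared
# across indices (spectrum, band, alpha threshold).
eval_index <- function(name, epoch, ctx, config) {
  switch(
    name,
    SpE = spectral_entropy(ctx$spectrum, ctx$band),
    SpG = spectral_gini(ctx$spectrum, ctx$band, degenerate = "na"),
    BSpG = bspg(binarize_spectrum(ctx$spectrum, ctx$band, ctx$alpha)),
    PE = permutation_entropy(epoch, m = config$pe.m, taus = config$pe.taus,
                             normalization = config$pe.normalization,
                             embedding = config$pe.embedding),
    AE = approximate_entropy(epoch, m = config$ae.m,
                             r_factor = config$ae.r_factor,
                             n_samples = config$ae.n),
    DFA = dfa_exponent(epoch, n_min_s = config$dfa.range_ms[1] / 1000,
                       n_max_s = config$dfa.range_ms[2] / 1000)$alpha,
    SFS = synch_fast_slow(subepochs_of(epoch, config$sfs.subepoch_s,
                                       config$sfs.overlap),
                          band_full = config$sfs.band_full_hz,
                          band_gamma = config$sfs.band_gamma_hz,
                          window = config$window),
    abort(paste0("unknown index: ", name))
  )
}

#' Compute depth-of-consciousness index series
#'
#' Runs the epoching pipeline over a (filtered) recording and evaluates the
#' requested indices on every epoch: 10 s epochs stepped by 5 s, Blackman
#' window, indices on the 0.8-47 Hz band, and a trailing 30 s moving-average
#' smoother — one value per 5 s. The BSpG threshold is calibrated from the
#' epochs wholly before the infusion start `t_I` (2% of the mean in-band bin
#' power), so BSpG requires `t_I` among the recording's events.
#'
#' @param x A [recording()], already low-pass filtered (see
#'   [lowpass_filter()]; [run_full_pipeline()] chains the two).
#' @param indices Character vector of index names among SpE, PE, AE, DFA,
#'   SFS, SpG, BSpG (default: all seven).
#' @param config A [doc_config()].
#'
#' @return A tibble with columns `index`, `time_s` (epoch end by default),
#'   `value`, `smoothed_value`.
#' @export
compute_index_series <- function(x, indices = index_names,
                                 config = doc_config()) {
  stopifnot(inherits(x, "doc_recording"))
  config <- as_doc_config(config)
  indices <- match.arg(indices, index_names, several.ok = TRUE)
  epochs <- epoch_stream(x, config$epoch.length_s, config$epoch.step_s)
  if (!length(epochs)) abort("recording shorter than one epoch")
  n_ep <- length(epochs)
  need_spec <- any(indices %in% c("SpE", "SpG", "BSpG"))
  band <- NULL
  spectra <- NULL
  if (need_spec) {
    n_fft <- length(epochs[[1]]$samples)
    band <- band_indices(x$fs, n_fft, config$indices.band_hz[1],
                         config$indices.band_hz[2])
    spectra <- lapply(epochs, power_spectrum, window = config$window,
                      demean = config$epoch.demean)
  }
  alpha <- NA_real_
  if ("BSpG" %in% indices) {
    t_I <- x$events$t_I
    if (is.null(t_I)) abort("BSpG needs event t_I to calibrate its threshold")
    pre <- which(vapply(epochs, function(e) {
      e$start_time + e$length <= t_I
    }, logical(1)))
    if (!length(pre)) abort("no complete epoch precedes t_I")
    base_band <- band_indices(x$fs, length(epochs[[1]]$samples),
                              config$bspg.baseline_band_hz[1],
                              config$bspg.baseline_band_hz[2])
    alpha <- calibrate_threshold(spectra[pre], base_band,
                                 config$bspg.threshold_fraction)
  }
  times <- vapply(epochs, function(e) {
    if (identical(config$timestamp, "center")) {
      e$start_time + e$length / 2
    } else {
      e$start_time + e$length
    }
  }, numeric(1))
  smooth_k <- max(1L, floor(config$smoothing_s / config$epoch.step_s))
  purrr::map_dfr(indices, function(nm) {
    vals <- vapply(seq_len(n_ep), function(i) {
      ctx <- list(spectrum = if (need_spec) spectra[[i]], band = band,
                  alpha = alpha)
      eval_index(nm, epochs[[i]], ctx, config)
    }, numeric(1))
    tibble::tibble(index = nm, time_s = times, value = vals,
                   smoothed_value = trailing_mean(vals, smooth_k))
  })
}

# Trailing moving average over the last k values (fewer at the start).
trailing_mean <- function(v, k) {
  if (k <= 1) return(v)
  cs <- cumsum(v)
  n <- length(v)
  i <- seq_len(n)
  lo <- pmax(1L, i - k + 1L)
  (cs - c(0, cs)[lo]) / (i - lo + 1L)
}

#' Anesthetic stage windows
#'
#' The four analysis stages: induction `[t_I, t_L]`, deep hypnosis
#' `[t_T - 20 min, t_T]`, awakened `[t_R - 20 min, t_R]`, and post
#' `[t_T + 40 min, t_T + 60 min]`.
#'
#' @param events Named list with `t_I`, `t_L`, `t_T`, `t_R` in seconds (as
#'   carried by a [recording()]).
#'
#' @return A tibble with columns `stage`, `start_s`, `end_s`.
#' @export
stage_windows <- function(events) {
  ev <- as.list(events)
  need <- c("t_I", "t_L", "t_T", "t_R")
  missing <- setdiff(need, names(ev))
  if (length(missing)) {
    abort(paste0("missing event(s): ", paste(missing, collapse = ", ")))
  }
  tibble::tibble(
    stage = factor(c("induction", "deep_hypnosis", "awakened", "post"),
                   levels = c("induction", "deep_hypnosis", "awakened",
                              "post")),
    start_s = c(ev$t_I, ev$t_T - 1200, ev$t_R - 1200, ev$t_T + 2400),
    end_s = c(ev$t_L, ev$t_T, ev$t_R, ev$t_T + 3600)
  )
}

#' Per-stage index statistics
#'
#' Median and 2.5/97.5 percentiles (linear-interpolation definition) of each
#' index within each stage window. Stages containing no samples are dropped
#' with a warning.
#'
#' @param series An index-series tibble from [compute_index_series()].
#' @param windows A tibble from [stage_windows()].
#' @param use_smoothed Summarize the smoothed values (default `TRUE`).
#'
#' @return A tibble with `index`, `stage`, `n`, `median`, `p2.5`, `p97.5`.
#' @export
stage_statistics <- function(series, windows, use_smoothed = TRUE) {
  col <- if (use_smoothed) "smoothed_value" else "value"
  out <- purrr::map_dfr(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    sub <- dplyr::filter(series, .data$time_s >= w$start_s,
                         .data$time_s <= w$end_s)
    if (!nrow(sub)) return(NULL)
    dplyr::summarise(
      dplyr::group_by(sub, .data$index),
      stage = w$stage,
      n = dplyr::n(),
      median = median(.data[[col]], na.rm = TRUE),
      p2.5 = quantile(.data[[col]], 0.025, na.rm = TRUE, names = FALSE),
      p97.5 = quantile(.data[[col]], 0.975, na.rm = TRUE, names = FALSE),
      .groups = "drop")
  })
  empty <- setdiff(as.character(windows$stage), as.character(out$stage))
  if (length(empty)) {
    warn(paste0("stage(s) with no samples dropped: ",
                paste(empty, collapse = ", ")))
  }
  out
}

#' Select index samples on the clinical sampling schedule
#'
#' Thins an index series to the blood-sampling-style schedule: after the
#' infusion start, every 30 s for 10 min then every 1 min for 60 min; after
#' the infusion end, every 30 s for 30 min, every 1 min for the next 20 min,
#' and every 2 min for the final 20 min. Each scheduled instant takes the
#' nearest-in-time series value; instants beyond the series are dropped with
#' a warning.
#'
#' @param series An index-series tibble from [compute_index_series()].
#' @param t_I,t_T Infusion start and end, seconds.
#'
#' @return The schedule subset of `series`, with a `scheduled_s` column.
#' @export
select_index_samples <- function(series, t_I, t_T) {
  post_start <- c(seq(t_I + 30, t_I + 600, by = 30),
                  seq(t_I + 660, t_I + 4200, by = 60))
  post_end <- c(seq(t_T + 30, t_T + 1800, by = 30),
                seq(t_T + 1860, t_T + 3000, by = 60),
                seq(t_T + 3120, t_T + 4200, by = 120))
  sched <- sort(unique(c(post_start, post_end)))
  sched <- sched[sched >= t_I]
  tmax <- max(series$time_s)
  if (any(sched > tmax)) {
    warn("sampling schedule truncated at the end of the series")
    sched <- sched[sched <= tmax]
  }
  purrr::map_dfr(unique(series$index), function(nm) {
    sub <- dplyr::filter(series, .data$index == nm)
    pick <- vapply(sched, function(s) which.min(abs(sub$time_s - s)),
                   integer(1))
    dplyr::mutate(sub[pick, ], scheduled_s = sched)
  })
}

#' Plot index series
#'
#' @param series An index-series tibble from [compute_index_series()].
#' @param events Optional named list of event times (seconds) drawn as
#'   vertical dashed lines.
#' @return A ggplot, one facet per index.
#' @export
plot_index_series <- function(series, events = NULL) {
  p <- ggplot2::ggplot(series,
                       ggplot2::aes(x = .data$time_s / 60,
                                    y = .data$smoothed_value)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$value),
                       colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~ index, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = "index value") +
    ggplot2::theme_minimal()
  if (!is.null(events) && length(events)) {
    ev <- tibble::tibble(name = names(unlist(events)),
                         t = unlist(events) / 60)
    p <- p + ggplot2::geom_vline(data = ev,
                                 ggplot2::aes(xintercept = .data$t),
                                 linetype = "dashed", colour = "grey40")
  }
  p
}
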
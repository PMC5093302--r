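#' Run the complete analysis on one subject
#'
#' Chains the whole pipeline: low-pass filter, epoching, every requested
#' index, trailing smoothing, stage statistics (when all four events are
#' known), and — when a concentration course is available — the clinical
#' sampling schedule plus Spearman correlation and prediction probability of
#' each index against effect-site concentration.
#'
#' @param input A `doc_subject` from [generate_subject()], or a
#'   [recording()] (carrying events for stage statistics / BSpG).
#' @param conc Optional concentration tibble (`time_min`, `ce`); taken from
#'   the subject when `input` is a `doc_subject`.
#' @param indices Indices to compute (default: all seven).
#' @param config A [doc_config()].
#' @param n_boot Bootstrap resamples for the prediction-probability SE.
#'
#' @return A `doc_report`: list with `series` (per-epoch index tibble),
#'   `stages` (per-stage statistics or `NULL`), `samples` (schedule subset
#'   or `NULL`), `metrics` (per-index `spearman`, `somers_d`, `pk`, `pk_se`
#'   or `NULL`), and `config` (the configuration actually used).
#' @export
run_full_pipeline <- function(input, conc = NULL, indices = index_names,
                              config = doc_config(), n_boot = 200) {
  config <- as_doc_config(config)
  if (inherits(input, "doc_subject")) {
    rec <- input$recording
    if (is.null(conc)) conc <- input$conc
  } else if (inherits(input, "doc_recording")) {
    rec <- input
  } else {
    abort("`input` must be a doc_subject or doc_recording")
  }
  filtered <- lowpass_filter(rec, order = config$filter.order,
                             cutoff = config$filter.cutoff_hz,
                             zero_phase = config$filter.zero_phase)
  series <- compute_index_series(filtered, indices, config)
  ev <- rec$events
  stages <- NULL
  if (all(c("t_I", "t_L", "t_T", "t_R") %in% names(ev))) {
    stages <- stage_statistics(series, stage_windows(ev))
  }
  samples <- NULL
  metrics <- NULL
  if (!is.null(conc) && !is.null(ev$t_I) && !is.null(ev$t_T)) {
    samples <- select_index_samples(series, ev$t_I, ev$t_T)
    ce_at <- approx(conc$time_min * 60, conc$ce, xout = unique(samples$scheduled_s),
                    rule = 2)$y
    metrics <- purrr::map_dfr(unique(samples$index), function(nm) {
      sub <- dplyr::filter(samples, .data$index == nm)
      ok <- is.finite(sub$smoothed_value)
      pp <- prediction_probability(sub$smoothed_value[ok], ce_at[ok],
                                   n_boot = n_boot)
      tibble::tibble(index = nm,
                     spearman = spearman_rho(sub$smoothed_value[ok],
                                             ce_at[ok]),
                     somers_d = pp$somers_d, pk = pp$pk, pk_se = pp$se,
                     n = sum(ok))
    })
  }
  structure(list(series = series, stages = stages, samples = samples,
                 metrics = metrics, config = config),
            class = "doc_report")
}

#' @export
print.doc_report <- function(x, ...) {
  cat("<doc_report>\n")
  cat(sprintf("  series: %d values across %d index(es)\n",
              nrow(x$series), length(unique(x$series$index))))
  if (!is.null(x$stages)) cat(sprintf("  stages: %d rows\n", nrow(x$stages)))
  if (!is.null(x$metrics)) {
    cat("  metrics:\n")
    print(x$metrics)
  }
  invisible(x)
}
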
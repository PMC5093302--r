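#' Analysis configuration
#'
#' Bundles every tunable of the index pipeline with its default. Defaults
#' reproduce the reference processing protocol: a 9th-order Butterworth
#' low-pass at 48 Hz, 10 s epochs stepped by 5 s, a Blackman window, indices
#' evaluated on the 0.8-47 Hz band, a 30 s trailing moving-average smoother,
#' and a binarization threshold equal to 2% of the mean pre-infusion in-band
#' bin power.
#'
#' @param ... Named overrides of the defaults listed below. Unknown keys are
#'   an error, so typos do not silently fall back to defaults.
#'
#' @return A named list of class `doc_config`.
#'
#' @details Keys and defaults:
#' \describe{
#'   \item{`filter.order` = 9, `filter.cutoff_hz` = 48}{low-pass filter.}
#'   \item{`filter.zero_phase` = TRUE}{forward-backward (zero-phase)
#'     application; set `FALSE` for single-pass causal filtering.}
#'   \item{`epoch.length_s` = 10, `epoch.step_s` = 5}{epoching.}
#'   \item{`window` = "blackman"}{epoch taper, or "rectangular".}
#'   \item{`epoch.demean` = FALSE}{subtract the epoch mean before windowing.}
#'   \item{`indices.band_hz` = c(0.8, 47)}{analysis band for SpE, SpG, BSpG.}
#'   \item{`bspg.threshold_fraction` = 0.02, `bspg.baseline_band_hz` =
#'     c(0.8, 47)}{BSpG binarization threshold calibration.}
#'   \item{`pe.m` = 3, `pe.taus` = c(1, 2), `pe.normalization` =
#'     "two_log_mfact"}{permutation entropy; the alternative normalization
#'     `"log_mp1fact_half"` divides by log((m+1)!/2).}
#'   \item{`pe.embedding` = "standard"}{`m`-point ordinal vectors spanning
#'     (m-1)*tau samples; `"extended"` uses m+1 points spanning m*tau.}
#'   \item{`ae.n` = 1024, `ae.m` = 2, `ae.r_factor` = 0.2}{approximate
#'     entropy (evaluated on the final `ae.n` samples of each epoch).}
#'   \item{`dfa.range_ms` = c(6.7, 157.8), `dfa.n_scales` = 12}{DFA segment
#'     lengths.}
#'   \item{`sfs.subepoch_s` = 2, `sfs.overlap` = 0.5, `sfs.band_full_hz` =
#'     c(0.5, 47), `sfs.band_gamma_hz` = c(40, 47)}{SynchFastSlow.}
#'   \item{`smoothing_s` = 30}{trailing moving-average span for index series.}
#'   \item{`timestamp` = "end"}{stamp each epoch's value at its end
#'     (causal) or "center".}
#'   \item{`gini.degenerate` = "error"}{behaviour of gini/SpG on an all-zero
#'     input: "error" or "na".}
#'   \item{`pk.weight_ref` = 58}{weight scaling reference in the clearance
#'     covariate model (58 or 63; both appear in the source model tables).}
#' }
#' @examples
#' cfg <- doc_config(epoch.length_s = 5)
#' cfg$epoch.length_s
#' @export
doc_config <- function(...) {
  defaults <- list(
    filter.order = 9,
    filter.cutoff_hz = 48,
    filter.zero_phase = TRUE,
    epoch.length_s = 10,
    epoch.step_s = 5,
    window = "blackman",
    epoch.demean = FALSE,
    indices.band_hz = c(0.8, 47),
    bspg.threshold_fraction = 0.02,
    bspg.baseline_band_hz = c(0.8, 47),
    pe.m = 3,
    pe.taus = c(1, 2),
    pe.normalization = "two_log_mfact",
    pe.embedding = "standard",
    ae.n = 1024,
    ae.m = 2,
    ae.r_factor = 0.2,
    dfa.range_ms = c(6.7, 157.8),
    dfa.n_scales = 12,
    sfs.subepoch_s = 2,
    sfs.overlap = 0.5,
    sfs.band_full_hz = c(0.5, 47),
    sfs.band_gamma_hz = c(40, 47),
    smoothing_s = 30,
    timestamp = "end",
    gini.degenerate = "error",
    pk.weight_ref = 58
  )
  override <- list(...)
  if (length(override)) {
    if (is.null(names(override)) || any(names(override) == "")) {
      abort("all configuration overrides must be named")
    }
    unknown <- setdiff(names(override), names(defaults))
    if (length(unknown)) {
      abort(paste0("unknown configuration key(s): ",
                   paste(unknown, collapse = ", ")))
    }
    defaults[names(override)] <- override
  }
  structure(defaults, class = "doc_config")
}

#' @export
print.doc_config <- function(x, ...) {
  cat("<doc_config>\n")
  for (k in names(x)) {
    cat(sprintf("  %-26s %s\n", k, paste(format(x[[k]]), collapse = ", ")))
  }
  invisible(x)
}

as_doc_config <- function(config) {
  if (inherits(config, "doc_config")) return(config)
  if (is.null(config)) return(doc_config())
  do.call(doc_config, as.list(config))
}
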
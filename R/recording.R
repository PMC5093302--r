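#' EEG recording container
#'
#' A single-channel EEG trace with its sampling rate and, optionally, the
#' anesthesia event times: infusion start `t_I`, loss of consciousness `t_L`,
#' infusion end `t_T`, and recovery of consciousness `t_R` (seconds from the
#' start of the record).
#'
#' @param samples Numeric vector of amplitudes (conventionally microvolts).
#' @param fs Sampling rate in Hz (positive scalar).
#' @param events Optional named list/vector with any of `t_I`, `t_L`, `t_T`,
#'   `t_R` in seconds. When several are present they must be ordered
#'   `t_I < t_L < t_T < t_R` and lie within the record.
#'
#' @return An object of class `doc_recording`: a list with elements
#'   `samples`, `fs`, `events`.
#' @examples
#' rec <- recording(sin(2 * pi * 10 * (0:2559) / 256), fs = 256)
#' rec
#' @export
recording <- function(samples, fs, events = list()) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a positive finite scalar")
  }
  if (!all(is.finite(samples))) {
    abort("`samples` must be finite")
  }
  events <- as.list(events)
  allowed <- c("t_I", "t_L", "t_T", "t_R")
  if (length(events)) {
    bad <- setdiff(names(events), allowed)
    if (length(bad)) {
      abort(paste0("unknown event name(s): ", paste(bad, collapse = ", ")))
    }
    dur <- length(samples) / fs
    ev <- unlist(events)
    if (any(ev < 0 | ev > dur)) {
      abort("event times must lie within the record duration")
    }
    present <- allowed[allowed %in% names(events)]
    ord <- unlist(events[present])
    if (is.unsorted(ord, strictly = TRUE)) {
      abort("event times must satisfy t_I < t_L < t_T < t_R")
    }
  }
  structure(list(samples = samples, fs = fs, events = events),
            class = "doc_recording")
}

#' @export
print.doc_recording <- function(x, ...) {
  cat(sprintf("<doc_recording> %d samples @ %g Hz (%.1f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  if (length(x$events)) {
    ev <- unlist(x$events)
    cat("  events:", paste(sprintf("%s=%g s", names(ev), ev), collapse = ", "),
        "\n")
  }
  invisible(x)
}

duration_s <- function(x) length(x$samples) / x$fs

#' Low-pass filter a recording
#'
#' Butterworth low-pass filtering of an EEG recording, by default the
#' 9th-order, 48 Hz design used to suppress line noise and EMG above the
#' analysis band. Applied forward-backward (zero phase) by default so that
#' filtering does not delay index timestamps; set `zero_phase = FALSE` for a
#' single-pass causal filter.
#'
#' @param x A [recording()].
#' @param order Filter order (default 9).
#' @param cutoff Cutoff frequency in Hz (default 48); must be below Nyquist.
#' @param zero_phase Forward-backward application (default `TRUE`).
#'
#' @return A filtered `doc_recording` of identical length, rate and events.
#' @examples
#' rec <- recording(rnorm(2560), fs = 256)
#' filt <- lowpass_filter(rec)
#' @export
lowpass_filter <- function(x, order = 9, cutoff = 48, zero_phase = TRUE) {
  stopifnot(inherits(x, "doc_recording"))
  if (order < 1) abort("`order` must be >= 1")
  if (cutoff >= x$fs / 2) {
    abort("`cutoff` must be below the Nyquist frequency fs/2")
  }
  bf <- signal::butter(order, cutoff / (x$fs / 2), type = "low")
  y <- if (zero_phase) {
    # mirror padding absorbs the start-up transients of the forward and
    # backward passes (point reflection would pin the endpoint values,
    # since a zero-phase filter passes an antisymmetric neighbourhood
    # through its centre unchanged)
    s <- x$samples
    n <- length(s)
    np <- min(n - 1L, max(384L, 24L * order))
    padded <- c(s[(np + 1):2], s, s[(n - 1):(n - np)])
    out <- signal::filtfilt(bf, padded)
    out[(np + 1):(np + n)]
  } else {
    as.numeric(signal::filter(bf, x$samples))
  }
  recording(y, x$fs, x$events)
}

#' Split a recording into overlapping epochs
#'
#' Epochs start at 0, `step`, 2*`step`, ... seconds; each holds exactly
#' `round(epoch_len * fs)` samples. A trailing stretch too short for a full
#' epoch is discarded. Defaults are 10 s epochs stepped by 5 s (50% overlap),
#' i.e. one index value every 5 s.
#'
#' @param x A [recording()].
#' @param epoch_len Epoch length in seconds (default 10).
#' @param step Epoch step in seconds (default 5); `0 < step <= epoch_len`.
#'
#' @return A list of epochs, each of class `doc_epoch`: a list with
#'   `samples`, `fs`, `start_time`, `length`. An empty list (with a warning)
#'   if the record is shorter than one epoch.
#' @examples
#' rec <- recording(rnorm(256 * 60), fs = 256)
#' length(epoch_stream(rec)) # 11
#' @export
epoch_stream <- function(x, epoch_len = 10, step = 5) {
  stopifnot(inherits(x, "doc_recording"))
  if (epoch_len <= 0) abort("`epoch_len` must be positive")
  if (step <= 0 || step > epoch_len) {
    abort("`step` must satisfy 0 < step <= epoch_len")
  }
  n_ep <- round(epoch_len * x$fs)
  n <- length(x$samples)
  if (n < n_ep) {
    warn("record shorter than one epoch; returning no epochs")
    return(list())
  }
  n_step <- step * x$fs
  count <- floor((n - n_ep) / n_step) + 1L
  lapply(seq_len(count) - 1L, function(i) {
    from <- round(i * n_step) + 1L
    structure(list(samples = x$samples[from:(from + n_ep - 1L)],
                   fs = x$fs,
                   start_time = i * step,
                   length = epoch_len),
              class = "doc_epoch")
  })
}

epoch_samples <- function(e) {
  if (inherits(e, "doc_epoch")) e$samples else as.numeric(e)
}

#' Read / write a recording as CSV
#'
#' The canonical interchange format is a small CSV: comment header lines
#' `# fs: <Hz>` and `# units: <str>` followed by a single `value` column
#' (or `time,value`, in which case the time spacing is checked against the
#' declared rate). Event times, if any, travel in a separate JSON file, see
#' [run_full_pipeline()].
#'
#' @param path File path.
#' @param x A [recording()] (for writing).
#' @param events Optional events to attach on read (named list, seconds).
#'
#' @return `read_recording_csv()` returns a `doc_recording`;
#'   `write_recording_csv()` returns `path` invisibly.
#' @export
read_recording_csv <- function(path, events = list()) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  hdr <- readLines(path, n = 10L)
  fs_line <- grep("^#\\s*fs\\s*:", hdr, value = TRUE)
  if (!length(fs_line)) abort("missing '# fs: <Hz>' header line")
  fs <- as.numeric(sub("^#\\s*fs\\s*:\\s*", "", fs_line[1]))
  if (!is.finite(fs) || fs <= 0) abort("malformed fs header")
  dat <- read.csv(path, comment.char = "#")
  if ("time" %in% names(dat)) {
    dt <- diff(dat$time)
    if (any(dt <= 0)) abort("non-monotone time column")
    if (abs(stats::median(dt) - 1 / fs) / (1 / fs) > 0.001) {
      abort("time column spacing disagrees with declared fs by > 0.1%")
    }
  }
  col <- if ("value" %in% names(dat)) dat$value else dat[[ncol(dat)]]
  recording(col, fs, events)
}

#' @rdname read_recording_csv
#' @export
write_recording_csv <- function(x, path) {
  stopifnot(inherits(x, "doc_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fs: %.10g", x$fs), "# units: uV"), con)
  write.csv(data.frame(value = x$samples), con, row.names = FALSE)
  invisible(path)
}
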
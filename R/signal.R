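#' Construct a multichannel signal record
#'
#' A `signal_record` bundles a channels-by-samples numeric matrix with its
#' sampling rate, subject/context labels, optional event annotations and an
#' optional scalar behaviour channel (e.g. lever pressure) sampled in lockstep
#' with the neural channels.
#'
#' Annotation intervals are 0-based, half-open `[start, end)` sample indices.
#'
#' @param samples Numeric matrix, channels x samples.
#' @param fs Sampling rate in Hz (> 0).
#' @param subject_id,context_id Labels attached to the record.
#' @param annotations Optional tibble/data frame with columns `label`,
#'   `start_sample`, `end_sample` (half-open, 0-based).
#' @param scalar Optional numeric vector of length `ncol(samples)` carrying a
#'   behaviour measurement per sample.
#' @return An object of class `signal_record`.
#' @export
signal_record <- function(samples, fs, subject_id = "s1", context_id = "c1",
                          annotations = NULL, scalar = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1L)
  if (!is.matrix(samples) || !is.numeric(samples)) {
    abort("`samples` must be a numeric matrix (channels x samples)")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    abort("`fs` must be a positive scalar (Hz)")
  }
  n <- ncol(samples)
  if (!is.null(annotations)) {
    annotations <- tibble::as_tibble(annotations)
    req <- c("label", "start_sample", "end_sample")
    if (!all(req %in% names(annotations))) {
      abort("annotations need columns label, start_sample, end_sample")
    }
    bad <- annotations$start_sample < 0 | annotations$end_sample > n |
      annotations$start_sample >= annotations$end_sample
    if (any(bad)) abort("annotation intervals must satisfy 0 <= start < end <= n_samples")
  }
  if (!is.null(scalar) && length(scalar) != n) {
    abort("`scalar` must have one value per sample")
  }
  structure(
    list(samples = samples, fs = fs, subject_id = subject_id,
         context_id = context_id, annotations = annotations, scalar = scalar),
    class = "signal_record"
  )
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("<signal_record> %d channel(s) x %d samples @ %g Hz  subject=%s context=%s\n",
              nrow(x$samples), ncol(x$samples), x$fs, x$subject_id, x$context_id))
  if (!is.null(x$annotations)) cat(sprintf("  %d annotated interval(s)\n", nrow(x$annotations)))
  if (!is.null(x$scalar)) cat("  scalar behaviour channel present\n")
  invisible(x)
}

#' Zero-phase Butterworth bandpass filter
#'
#' Filters every channel of a record independently with a Butterworth bandpass
#' design applied forward and backward (`signal::filtfilt`), so the output is
#' zero-phase and the effective magnitude response is the squared one-pass
#' response (the effective order is doubled). The default 0.5--300 Hz band with
#' a second-order design isolates the local field potential from raw wideband
#' recordings.
#'
#' @param record A [signal_record()].
#' @param low,high Band edges in Hz; requires `0 < low < high < fs/2`.
#' @param order Butterworth design order (>= 1).
#' @return A filtered `signal_record` with all metadata preserved.
#' @export
bandpass_filter <- function(record, low = 0.5, high = 300, order = 2) {
  stopifnot(inherits(record, "signal_record"))
  fs <- record$fs
  if (ncol(record$samples) == 0L) abort("cannot filter an empty signal")
  if (!(low > 0 && high > low)) abort("need 0 < low < high")
  if (high >= fs / 2) abort(sprintf("high edge %g Hz must be below Nyquist (%g Hz)", high, fs / 2))
  if (order < 1) abort("`order` must be >= 1")
  filt <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  out <- record
  out$samples <- t(apply(record$samples, 1L, function(ch) signal::filtfilt(filt, ch)))
  # apply() drops dims for single-sample signals; restore shape
  dim(out$samples) <- dim(record$samples)
  out
}

#' Keep the behaviour-relevant segments of a record
#'
#' Three segmentation modes cover the typical behaviour paradigms: `"all"`
#' keeps the whole record (continuous behaviours such as running),
#' `"intervals"` concatenates the annotated intervals in temporal order
#' (discrete trials such as reach-and-grab), and `"threshold"` keeps samples
#' whose scalar behaviour channel is at or above `threshold` (e.g. lever
#' pressure), concatenated temporally.
#'
#' @param record A [signal_record()].
#' @param mode One of `"all"`, `"intervals"`, `"threshold"`.
#' @param threshold Scalar cut-off, required for `mode = "threshold"`. The
#'   appropriate value is paradigm-specific and must be supplied explicitly.
#' @return A `signal_record` containing only the selected samples.
#' @export
segment_behavior <- function(record, mode = c("all", "intervals", "threshold"),
                             threshold = NULL) {
  stopifnot(inherits(record, "signal_record"))
  mode <- match.arg(mode)
  if (mode == "all") return(record)
  if (mode == "intervals") {
    ann <- record$annotations
    if (is.null(ann) || nrow(ann) == 0L) abort("mode='intervals' requires annotations")
    ann <- ann[order(ann$start_sample), , drop = FALSE]
    idx <- unlist(purrr::map2(ann$start_sample, ann$end_sample,
                              function(s, e) seq.int(s + 1L, e)))
  } else {
    if (is.null(record$scalar)) abort("mode='threshold' requires a scalar behaviour channel")
    if (is.null(threshold)) abort("mode='threshold' requires an explicit `threshold`")
    idx <- which(record$scalar >= threshold)
  }
  if (length(idx) == 0L) {
    abort(sprintf("segmentation left no samples for subject %s, context %s",
                  record$subject_id, record$context_id))
  }
  out <- record
  out$samples <- record$samples[, idx, drop = FALSE]
  out$scalar <- if (!is.null(record$scalar)) record$scalar[idx]
  out$annotations <- NULL
  out
}

#' Cut a record into fixed-length, non-overlapping trials
#'
#' Consecutive windows of `trial_seconds` are taken from the (concatenated)
#' signal; a trailing remainder shorter than one trial is discarded. Trials do
#' not overlap, which keeps them statistically independent for the downstream
#' Gaussian fits.
#'
#' @param record A [signal_record()].
#' @param trial_seconds Trial duration in seconds (default 2).
#' @return A `trial_set`: channels x samples x trials array plus metadata.
#' @export
frame_trials <- function(record, trial_seconds = 2) {
  stopifnot(inherits(record, "signal_record"))
  len <- as.integer(round(trial_seconds * record$fs))
  n <- ncol(record$samples)
  if (n < len) {
    abort(sprintf("record (%d samples) is shorter than one %g-s trial (%d samples)",
                  n, trial_seconds, len))
  }
  k <- n %/% len
  arr <- array(record$samples[, seq_len(k * len), drop = FALSE],
               dim = c(nrow(record$samples), len, k))
  structure(
    list(trials = arr, trial_seconds = trial_seconds, fs = record$fs,
         subject_id = record$subject_id, context_id = record$context_id),
    class = "trial_set"
  )
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$trials)
  cat(sprintf("<trial_set> %d trial(s) of %g s (%d samples) x %d channel(s) @ %g Hz\n",
              d[3], x$trial_seconds, d[2], d[1], x$fs))
  invisible(x)
}
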
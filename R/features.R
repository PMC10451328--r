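#' Classical frequency bands
#'
#' The five canonical LFP/EEG bands used throughout the package. The gamma
#' upper edge is capped at `min(300, fs/2)` when features are computed, so the
#' same definitions apply at any sampling rate.
#'
#' @return Named list of `c(low, high)` band edges in Hz.
#' @export
classical_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 12),
       beta = c(12, 30), gamma = c(30, 300))
}

#' Per-trial log band-power features
#'
#' For each trial and channel, Hanning-tapered windows of `window_points`
#' samples are slid along the trial at a hop of `hop_seconds`; each window is
#' Fourier transformed and the squared spectral magnitudes are summed over the
#' bins whose centre frequency falls in each band. Window band powers are
#' averaged within the trial and natural-log transformed. A sixth feature per
#' channel, the log of the sum of the five band powers, is appended, so the
#' output has `6 * n_channels` feature columns.
#'
#' With `per_window = TRUE` each window contributes its own row instead of
#' being averaged, which is useful for sensitivity analyses; the default
#' trial-averaged form is what the downstream Gaussian fits expect.
#'
#' @param trials A `trial_set` from [frame_trials()].
#' @param bands Named list of `c(low, high)` Hz edges; defaults to
#'   [classical_bands()].
#' @param window_points Samples per spectral window (default 512).
#' @param hop_seconds Hop between window starts in seconds (default 0.1).
#' @param per_window Emit one row per window rather than per trial.
#' @param power_floor Band powers are floored at this value before the log so
#'   degenerate all-zero channels stay finite (they are flagged with a
#'   warning).
#' @return A tibble: metadata columns (`subject_id`, `context_id`, `trial`)
#'   plus one numeric column per (channel, band) feature, named e.g.
#'   `ch01_delta`, ..., `ch01_sum`.
#' @export
band_power_features <- function(trials, bands = classical_bands(),
                                window_points = 512, hop_seconds = 0.1,
                                per_window = FALSE, power_floor = 1e-300) {
  stopifnot(inherits(trials, "trial_set"))
  d <- dim(trials$trials)
  n_chan <- d[1]; trial_len <- d[2]; n_trials <- d[3]
  fs <- trials$fs
  if (length(bands) == 0L) abort("need at least one band")
  if (window_points > trial_len) {
    abort(sprintf("window (%d points) longer than trial (%d samples)", window_points, trial_len))
  }
  nyq <- fs / 2
  band_mat <- vapply(bands, function(b) c(b[1], min(b[2], nyq)), numeric(2))
  if (any(band_mat[2, ] <= band_mat[1, ])) abort("empty band after Nyquist capping")

  hop <- max(1L, as.integer(round(hop_seconds * fs)))
  starts <- seq.int(1L, trial_len - window_points + 1L, by = hop)
  win <- 0.5 - 0.5 * cos(2 * pi * seq.int(0L, window_points - 1L) / (window_points - 1L))
  freqs <- (seq_len(window_points) - 1L) * fs / window_points
  half <- seq_len(window_points %/% 2 + 1L)
  bin_sets <- lapply(seq_along(bands), function(b) {
    which(freqs[half] >= band_mat[1, b] & freqs[half] < band_mat[2, b])
  })
  if (any(lengths(bin_sets) == 0L)) abort("a band contains no FFT bins at this resolution")

  band_names <- names(bands)
  if (is.null(band_names)) band_names <- paste0("band", seq_along(bands))
  labels <- as.vector(t(outer(sprintf("ch%02d", seq_len(n_chan)),
                              c(band_names, "sum"), paste, sep = "_")))

  one_trial <- function(t_idx) {
    # windows x channels band powers, averaged across windows per channel
    out <- matrix(0, nrow = n_chan, ncol = length(bands))
    seg <- trials$trials[, , t_idx, drop = FALSE]
    for (ch in seq_len(n_chan)) {
      wp <- matrix(0, nrow = length(starts), ncol = length(bands))
      for (w in seq_along(starts)) {
        x <- seg[ch, starts[w]:(starts[w] + window_points - 1L), 1L] * win
        spec <- abs(fft(x)[half])^2
        wp[w, ] <- vapply(bin_sets, function(idx) sum(spec[idx]), numeric(1))
      }
      out[ch, ] <- colMeans(wp)
    }
    out
  }

  rows <- vector("list", n_trials)
  degenerate <- FALSE
  for (t_idx in seq_len(n_trials)) {
    bp <- one_trial(t_idx)                      # channels x bands
    if (any(bp < power_floor)) degenerate <- TRUE
    bp <- pmax(bp, power_floor)
    feat <- cbind(log(bp), log(pmax(rowSums(bp), power_floor)))
    rows[[t_idx]] <- as.vector(t(feat))          # channel-major, band then sum
  }
  if (degenerate) warn("some band powers were zero and were floored before the log")

  values <- do.call(rbind, rows)
  colnames(values) <- labels
  tibble::tibble(
    subject_id = trials$subject_id,
    context_id = trials$context_id,
    trial = seq_len(n_trials)
  ) |>
    dplyr::bind_cols(tibble::as_tibble(values))
}

#' Enumerate all unordered feature pairs
#'
#' The quantizer operates on two-dimensional feature combinations. All
#' `F * (F - 1) / 2` unordered pairs are enumerated in lexicographic order of
#' the (i, j) index pair (i < j), which makes `pair_id` deterministic and
#' stable across runs; 96 features yield 4560 pairs.
#'
#' @param features A trial feature tibble, or an integer feature count.
#' @return A tibble with columns `pair_id`, `i`, `j` (1-based feature column
#'   indices) and `feature_i`, `feature_j` labels when names are available.
#' @export
pair_features <- function(features) {
  if (is.numeric(features) && length(features) == 1L) {
    nf <- as.integer(features)
    labels <- NULL
  } else {
    labels <- feature_cols(features)
    nf <- length(labels)
  }
  if (nf < 2L) abort("need at least two features to form pairs")
  cmb <- combn(nf, 2L)
  out <- tibble::tibble(pair_id = seq_len(ncol(cmb)), i = cmb[1, ], j = cmb[2, ])
  if (!is.null(labels)) {
    out$feature_i <- labels[out$i]
    out$feature_j <- labels[out$j]
  }
  out
}
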
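#' Simulate a feature-level cohort
#'
#' Draws a nested-Gaussian population that mirrors the statistical structure
#' the quantizer assumes: per context, each subject's per-feature mean is
#' drawn from `N(0, between_subject_std^2)` and its trials from
#' `N(mean, within_subject_std^2)` with independent features. With
#' `context_independence = TRUE` (the default) subject means are redrawn
#' independently per context, which is what makes re-enrollment under a new
#' behaviour yield an independent key (revocability). Output is bit-identical
#' for a given seed.
#'
#' Defaults mirror the study scale: 10 subjects, 96 features (16 channels
#' x 6 band features), 200 trials per context, between-subject spread 10x the
#' within-subject trial noise.
#'
#' @param n_subjects,n_trials,n_features,n_contexts Cohort dimensions.
#' @param between_subject_std Spread of subject means per feature.
#' @param within_subject_std Trial noise around each subject mean.
#' @param context_independence Redraw subject means per context.
#' @param seed Integer seed.
#' @return A trial feature tibble with `subject_id`, `context_id`, `trial`
#'   and feature columns `f001`, `f002`, ...
#' @export
simulate_feature_cohort <- function(n_subjects = 10, n_trials = 200,
                                    n_features = 96, n_contexts = 1,
                                    between_subject_std = 10,
                                    within_subject_std = 1,
                                    context_independence = TRUE,
                                    seed = 1L) {
  if (n_subjects < 1 || n_trials < 1 || n_features < 1 || n_contexts < 1) {
    abort("all cohort counts must be >= 1")
  }
  if (between_subject_std < 0 || within_subject_std < 0) {
    abort("spreads must be non-negative")
  }
  set.seed(seed)
  fnames <- sprintf("f%03d", seq_len(n_features))
  subjects <- sprintf("s%02d", seq_len(n_subjects))
  contexts <- sprintf("c%02d", seq_len(n_contexts))

  base_means <- matrix(rnorm(n_subjects * n_features, sd = between_subject_std),
                       n_subjects, n_features)
  out <- vector("list", n_contexts * n_subjects)
  k <- 0L
  for (ci in seq_len(n_contexts)) {
    mu <- if (context_independence && ci > 1L) {
      matrix(rnorm(n_subjects * n_features, sd = between_subject_std),
             n_subjects, n_features)
    } else base_means
    for (si in seq_len(n_subjects)) {
      trials <- matrix(rnorm(n_trials * n_features, sd = within_subject_std),
                       n_trials, n_features, byrow = TRUE)
      trials <- sweep(trials, 2L, mu[si, ], `+`)
      colnames(trials) <- fnames
      k <- k + 1L
      out[[k]] <- dplyr::bind_cols(
        tibble::tibble(subject_id = subjects[si], context_id = contexts[ci],
                       trial = seq_len(n_trials)),
        tibble::as_tibble(trials)
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Simulate raw multichannel band-shaped signals
#'
#' Generates per-subject broadband 1/f-shaped Gaussian noise whose power in
#' each classical band is scaled by a subject/channel/band-specific log-gain
#' offset, so the log band-power features of different subjects separate in
#' proportion to the spread of the offsets. This is a smoke-test surface for
#' the raw-signal path (filtering, framing, spectral features), not a
#' biophysically realistic LFP model.
#'
#' @param n_subjects Number of subjects.
#' @param n_channels Channels per record.
#' @param duration_s Record duration in seconds.
#' @param fs Sampling rate (Hz); must exceed twice the highest band edge used
#'   downstream.
#' @param gain_sd Standard deviation of the Gaussian the log-gain offsets are
#'   drawn from (natural-log power units). `gain_sd = 0` makes all subjects
#'   statistically identical.
#' @param gains Optional explicit offsets: list (per subject) of
#'   channels x 5 matrices (bands in [classical_bands()] order); overrides
#'   `gain_sd`.
#' @param bands Band definitions used for the shaping.
#' @param seed Integer seed.
#' @return A named list of [signal_record()]s, one per subject.
#' @export
simulate_signals <- function(n_subjects = 3, n_channels = 4, duration_s = 30,
                             fs = 1000, gain_sd = 1, gains = NULL,
                             bands = classical_bands(), seed = 1L) {
  set.seed(seed)
  n <- as.integer(round(duration_s * fs))
  nyq <- fs / 2
  band_mat <- vapply(bands, function(b) c(b[1], min(b[2], nyq)), numeric(2))
  if (any(band_mat[2, ] <= band_mat[1, ])) abort("fs too low for the requested bands")
  nb <- length(bands)
  if (is.null(gains)) {
    gains <- lapply(seq_len(n_subjects), function(i) {
      matrix(rnorm(n_channels * nb, sd = gain_sd), n_channels, nb)
    })
  }
  half <- seq_len(n %/% 2 - 1L)               # strictly positive, below Nyquist
  freqs <- half * fs / n
  band_of <- rep(NA_integer_, length(freqs))
  for (b in seq_len(nb)) {
    band_of[freqs >= band_mat[1, b] & freqs < band_mat[2, b]] <- b
  }
  base_amp <- 1 / sqrt(pmax(freqs, 0.5))       # 1/f power shaping, flattened below 0.5 Hz

  records <- lapply(seq_len(n_subjects), function(si) {
    sig <- matrix(0, n_channels, n)
    for (ch in seq_len(n_channels)) {
      amp <- base_amp
      g <- gains[[si]][ch, ]
      scale <- ifelse(is.na(band_of), 1, exp(g[pmax(band_of, 1L)] / 2))
      amp <- amp * scale
      z <- complex(real = rnorm(length(half)), imaginary = rnorm(length(half))) * amp
      spec <- complex(real = rep(0, n))
      spec[1L + half] <- z
      spec[n + 1L - half] <- Conj(z)
      sig[ch, ] <- Re(fft(spec, inverse = TRUE)) / sqrt(n)
    }
    signal_record(sig, fs = fs, subject_id = sprintf("s%02d", si))
  })
  names(records) <- sprintf("s%02d", seq_len(n_subjects))
  records
}
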
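# Shared fixtures and independent oracles.

# Numeric-integration oracle for the 1-D margin: the m solving
# integral_0^m N(0, sigma) = 1/2 - alpha, found by bisection.
oracle_margin_1d <- function(sigma, alpha, tol = 1e-10) {
  target <- 0.5 - alpha
  f <- function(m) {
    stats::integrate(function(x) stats::dnorm(x, 0, sigma), 0, m,
                     rel.tol = 1e-12, abs.tol = 1e-14)$value - target
  }
  lo <- 0; hi <- 20 * sigma
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Numeric oracle for the joint 2-D reading: shared standardized margin u such
# that the axis-aligned Gaussian mass over [0, u*sx] x [0, u*sy] (a product of
# two 1-D integrals computed numerically) equals 1/2 - alpha.
oracle_margin_2d_joint <- function(sigma_x, sigma_y, alpha, tol = 1e-10) {
  target <- 0.5 - alpha
  mass <- function(u) {
    ix <- stats::integrate(function(x) stats::dnorm(x, 0, sigma_x), 0, u * sigma_x,
                           rel.tol = 1e-12)$value
    iy <- stats::integrate(function(y) stats::dnorm(y, 0, sigma_y), 0, u * sigma_y,
                           rel.tol = 1e-12)$value
    ix * iy
  }
  lo <- 0; hi <- 20
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (mass(mid) < target) lo <- mid else hi <- mid
  }
  u <- (lo + hi) / 2
  c(m_x = u * sigma_x, m_y = u * sigma_y)
}

# Hand-constructed population model for controlled encoding/selection tests.
toy_model <- function(n_features, center = rep(0, n_features),
                      margin = 1, alpha = 0.3, bits = 2L) {
  fnames <- sprintf("f%03d", seq_len(n_features))
  pairs <- if (bits == 2L) pair_features(n_features) else
    tibble::tibble(pair_id = seq_len(n_features), i = seq_len(n_features))
  P <- nrow(pairs)
  mrg <- if (bits == 2L) cbind(m_x = rep(margin, P), m_y = rep(margin, P)) else
    cbind(m_x = rep(margin, P))
  structure(
    list(feature_names = fnames, bits_per_feature = bits, alpha = alpha,
         margin_convention = "independent",
         mu_pop = stats::setNames(center, fnames),
         sigma_pop = stats::setNames(rep(1, n_features), fnames),
         pairs = pairs, margin = mrg,
         worst_subject = rep("s01", P), usable = rep(TRUE, P),
         sigma_floor = 0, subjects = c("s01", "s02"), version = 1L),
    class = "population_model")
}

# Feature tibble with fixed rows for one subject.
toy_features <- function(mat, subject_id = "s01", context_id = "c01") {
  colnames(mat) <- sprintf("f%03d", seq_len(ncol(mat)))
  dplyr::bind_cols(
    tibble::tibble(subject_id = subject_id, context_id = context_id,
                   trial = seq_len(nrow(mat))),
    tibble::as_tibble(mat))
}

# Small well-separated cohort used across workflow tests.
small_cohort <- function(seed = 11L, n_subjects = 5, n_features = 12,
                         n_trials = 60, between = 10, within = 1,
                         n_contexts = 1) {
  simulate_feature_cohort(n_subjects = n_subjects, n_trials = n_trials,
                          n_features = n_features, n_contexts = n_contexts,
                          between_subject_std = between,
                          within_subject_std = within, seed = seed)
}

# A signal record holding given channel waveforms.
sine_record <- function(freq, fs, seconds = 2, channels = 1) {
  t <- seq(0, seconds - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * freq * t)
  signal_record(matrix(rep(x, channels), nrow = channels, byrow = TRUE), fs = fs)
}

rms <- function(x) sqrt(mean(x^2))
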
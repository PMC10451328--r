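as_key_matrix <- function(keys) {
  if (is.matrix(keys)) return(keys)
  if (inherits(keys, "bit_key")) keys <- list(keys)
  do.call(rbind, lapply(keys, function(k) {
    if (inherits(k, "bit_key")) k$bits else as.integer(k)
  }))
}

#' Authentication accuracy
#'
#' Fraction of genuine keys whose normalized Hamming distance to the template
#' is within the threshold (one key per presented sample or session).
#'
#' @param genuine_keys List of `bit_key`s (or a 0/1 matrix, one key per row).
#' @param template The subject's `key_template`.
#' @param gamma Optional threshold override.
#' @return Fraction in \[0, 1\].
#' @export
authentication_accuracy <- function(genuine_keys, template, gamma = NULL) {
  K <- as_key_matrix(genuine_keys)
  if (is.null(K) || nrow(K) == 0L) abort("need at least one genuine key")
  g <- if (!is.null(gamma)) gamma else template$gamma
  mean(hd_to_template(K, template$bits) <= g + 1e-12)
}

#' False acceptance rate
#'
#' Pooled fraction of impostor presentations accepted by a template: valid
#' keys over all samples of all other subjects, weighted by each subject's
#' sample count (i.e. a single pooled ratio, not a per-subject average).
#'
#' @param impostor_keys A list with one element per impostor subject, each a
#'   list of `bit_key`s (or 0/1 matrix); a flat list of keys also works.
#' @param template The attacked subject's `key_template`.
#' @param gamma Optional threshold override.
#' @return Pooled fraction in \[0, 1\].
#' @export
false_acceptance_rate <- function(impostor_keys, template, gamma = NULL) {
  if (length(impostor_keys) == 0L) abort("need at least one impostor subject")
  nested <- is.list(impostor_keys) &&
    all(vapply(impostor_keys, function(x) is.list(x) || is.matrix(x), logical(1))) &&
    !inherits(impostor_keys[[1]], "bit_key")
  mats <- if (nested) lapply(impostor_keys, as_key_matrix) else list(as_key_matrix(impostor_keys))
  K <- do.call(rbind, mats)
  if (is.null(K) || nrow(K) == 0L) abort("empty impostor pool")
  g <- if (!is.null(gamma)) gamma else template$gamma
  mean(hd_to_template(K, template$bits) <= g + 1e-12)
}

#' Min-entropy of a feature's code distribution
#'
#' `E = -delta * log2(max_i P_i)` where `P_i` are the code-symbol
#' probabilities and the normalizer `delta` is 1 for 1-bit codes and 1/2 for
#' 2-bit codes, so `E` is per-bit and lies in \[0, 1\]: 1 iff the distribution
#' is uniform over all symbols, 0 iff it is degenerate.
#'
#' @param counts Non-negative symbol counts (or probabilities); length 2 for
#'   1-bit codes, 4 for 2-bit codes.
#' @param bits_per_feature 1 or 2; inferred from `length(counts)` by default.
#' @return Min-entropy in \[0, 1\].
#' @export
min_entropy <- function(counts, bits_per_feature = NULL) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) abort("counts must be non-negative")
  tot <- sum(counts)
  if (tot <= 0) abort("all-zero code counts")
  if (is.null(bits_per_feature)) {
    bits_per_feature <- if (length(counts) >= 4L) 2L else 1L
  }
  delta <- if (bits_per_feature == 2L) 0.5 else 1
  -delta * log2(max(counts / tot))
}

#' Per-pair code distributions across the enrolled population
#'
#' For every enumerated feature pair (not only selected ones), each subject's
#' fitted training mean is sign-encoded against the population centre and the
#' resulting symbols are counted. Subjects falling inside a margin band still
#' contribute their quadrant sign, so the probabilities always sum to 1. This
#' is the distribution an attacker ignorant of the subject faces.
#'
#' @param enrollment An [enroll_cohort()] object.
#' @return A tibble, one row per pair, with a count column per code symbol.
#' @export
code_distribution <- function(enrollment) {
  stopifnot(inherits(enrollment, "nk_enrollment"))
  model <- enrollment$model
  M <- enrollment$subject_means                      # k x F
  x_hi <- sweep(M, 2L, model$mu_pop, `>`)
  pairs <- model$pairs
  if (model$bits_per_feature == 2L) {
    # symbol index per Gray-coded quadrant: 1=00, 2=01, 3=10, 4=11
    b1 <- !x_hi[, pairs$j, drop = FALSE]
    b2 <- x_hi[, pairs$i, drop = FALSE]
    sym <- 1L + 2L * b1 + 1L * b2                     # k x P in 1..4
    cnt <- vapply(1:4, function(v) colSums(sym == v), numeric(nrow(pairs)))
    if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = 1L)
    colnames(cnt) <- c("n00", "n01", "n10", "n11")
  } else {
    b <- x_hi[, pairs$i, drop = FALSE]
    cnt <- cbind(n0 = colSums(!b), n1 = colSums(b))
  }
  dplyr::bind_cols(pairs[, "pair_id"], tibble::as_tibble(cnt))
}

#' Average min-entropy over all feature pairs
#'
#' Arithmetic mean of the per-pair [min_entropy()] across every enumerated
#' pair — the population-level security summary of the code book.
#'
#' @param x An [enroll_cohort()] object, or a [code_distribution()] tibble.
#' @return Mean min-entropy in \[0, 1\].
#' @export
average_entropy <- function(x) {
  dist <- if (inherits(x, "nk_enrollment")) code_distribution(x) else x
  cnt <- as.matrix(dist[setdiff(names(dist), "pair_id")])
  bits <- if (ncol(cnt) >= 4L) 2L else 1L
  mean(apply(cnt, 1L, min_entropy, bits_per_feature = bits))
}
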
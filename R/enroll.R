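# Internal: per-subject reliable-pair selection, vectorised over all pairs.
# mu_s: subject feature means; X: subject training matrix (n x F).
# Returns integer pair_ids (ascending).
select_pairs_internal <- function(mu_s, X, model, beta) {
  pairs <- model$pairs
  d <- mu_s - model$mu_pop
  n <- nrow(X)
  D <- sweep(X, 2L, model$mu_pop)
  dx <- d[pairs$i]
  side_x <- sign(dx)
  m_x <- model$margin[, "m_x"]
  cond_mean <- abs(dx) >= m_x & side_x != 0
  Vx <- D[, pairs$i, drop = FALSE] *
    matrix(side_x, n, nrow(pairs), byrow = TRUE) >
    matrix(m_x, n, nrow(pairs), byrow = TRUE)
  if (model$bits_per_feature == 2L) {
    dy <- d[pairs$j]
    side_y <- sign(dy)
    m_y <- model$margin[, "m_y"]
    cond_mean <- cond_mean & abs(dy) >= m_y & side_y != 0
    Vy <- D[, pairs$j, drop = FALSE] *
      matrix(side_y, n, nrow(pairs), byrow = TRUE) >
      matrix(m_y, n, nrow(pairs), byrow = TRUE)
    frac <- colMeans(Vx & Vy)
  } else {
    frac <- colMeans(Vx)
  }
  pairs$pair_id[cond_mean & frac > beta & model$usable]
}

#' Select a subject's reliable feature pairs
#'
#' A pair is reliable for a subject when (a) the subject's fitted mean lies at
#' least one margin away from the population centre on every coded axis, and
#' (b) strictly more than a fraction `beta` of the subject's raw training
#' trials fall strictly inside the subject's code region (beyond the margins,
#' on the same side as the subject mean, on all axes). The selected pair
#' indices are the subject's helper data; they are not secret.
#'
#' @param features One subject's training trial feature tibble.
#' @param model A [build_population_model()] fit.
#' @param beta Minimum valid-sample proportion, in (0, 1].
#' @return A `helper_data` object: subject/context labels, sorted `pair_ids`,
#'   and the model version.
#' @export
select_reliable_features <- function(features, model, beta = 0.8) {
  stopifnot(inherits(model, "population_model"))
  if (beta <= 0 || beta > 1) abort("`beta` must lie in (0, 1]")
  sid <- unique(features$subject_id)
  if (length(sid) != 1L) abort("`features` must contain exactly one subject")
  if (!identical(feature_cols(features), model$feature_names)) {
    abort("feature columns do not match the population model")
  }
  X <- feature_matrix(features)
  fit <- fit_gaussian(X)
  ids <- select_pairs_internal(fit$mean, X, model, beta)
  structure(
    list(subject_id = sid,
         context_id = if ("context_id" %in% names(features)) unique(features$context_id)[1] else NA_character_,
         pair_ids = sort(ids), beta = beta, model_version = model$version),
    class = "helper_data"
  )
}

#' @export
print.helper_data <- function(x, ...) {
  cat(sprintf("<helper_data> subject=%s context=%s: %d selected pair(s)\n",
              x$subject_id, x$context_id, length(x$pair_ids)))
  invisible(x)
}

#' Encode one feature pair into a 2-bit code
#'
#' Quadrant encoding of a subject mean relative to the population centre. In
#' `"strict"` mode the margin bands are excluded: a mean inside any band is
#' `"undecidable"`. In `"sign"` mode the margins are ignored and only the
#' quadrant sign is coded; this is the rule applied at authentication, where
#' the centre — not the margin — is the decision boundary. The four codes
#' form a Gray code over the quadrants: `00` (x low, y high), `01` (x high,
#' y high), `10` (x low, y low), `11` (x high, y low).
#'
#' @param mean_pair Numeric `c(x, y)` subject mean.
#' @param center Numeric `c(cx, cy)` population centre.
#' @param margins Numeric `c(mx, my)`, non-negative.
#' @param mode `"strict"` or `"sign"`.
#' @return `"00"`, `"01"`, `"10"`, `"11"`, or `"undecidable"` (strict mode
#'   only).
#' @export
encode_feature <- function(mean_pair, center, margins = c(0, 0),
                           mode = c("strict", "sign")) {
  mode <- match.arg(mode)
  if (any(margins < 0)) abort("margins must be non-negative")
  x <- mean_pair[1]; y <- mean_pair[2]
  cx <- center[1]; cy <- center[2]
  if (mode == "strict") {
    mx <- margins[1]; my <- margins[2]
    x_hi <- x > cx + mx; x_lo <- x < cx - mx
    y_hi <- y > cy + my; y_lo <- y < cy - my
    if (!(x_hi || x_lo) || !(y_hi || y_lo)) return("undecidable")
  } else {
    x_hi <- x > cx; y_hi <- y > cy
  }
  # first bit: y below centre; second bit: x above centre
  paste0(as.integer(!y_hi), as.integer(x_hi))
}

# Internal: key bit matrix for raw trial rows X (n x F) against a helper's
# selected pairs, sign mode. One key per row; bits interleaved (y-bit, x-bit)
# per pair in helper order. 1-bit models emit one bit per selected feature.
key_bits_matrix <- function(X, helper, model) {
  sel <- helper$pair_ids
  if (length(sel) == 0L) return(matrix(integer(0), nrow = nrow(X), ncol = 0L))
  pr <- model$pairs[match(sel, model$pairs$pair_id), , drop = FALSE]
  x_hi <- sweep(X, 2L, model$mu_pop, `>`)
  if (model$bits_per_feature == 1L) {
    K <- x_hi[, pr$i, drop = FALSE]
    storage.mode(K) <- "integer"
    return(K)
  }
  b1 <- !x_hi[, pr$j, drop = FALSE]      # y below centre
  b2 <- x_hi[, pr$i, drop = FALSE]       # x above centre
  m <- length(sel)
  K <- matrix(0L, nrow = nrow(X), ncol = 2L * m)
  K[, seq(1L, 2L * m, by = 2L)] <- as.integer(b1)
  K[, seq(2L, 2L * m, by = 2L)] <- as.integer(b2)
  K
}

new_bit_key <- function(bits, subject_id) {
  structure(list(bits = as.integer(bits), subject_id = subject_id),
            class = "bit_key")
}

#' @export
print.bit_key <- function(x, ...) {
  cat(sprintf("<bit_key> %d bits, claimed subject=%s\n", length(x$bits), x$subject_id))
  invisible(x)
}

#' Generate a subject's key template
#'
#' Strict-encodes the subject's fitted training mean on every selected pair
#' and concatenates the 2-bit codes in helper order (key length =
#' `2 * n_selected`; `n_selected` for 1-bit models). Selection guarantees the
#' subject mean lies outside every margin band, so a strict-undecidable pair
#' indicates helper data inconsistent with the model and is an error. An empty
#' selection yields an empty template with a warning.
#'
#' @param features The subject's training trial feature tibble (the same
#'   trials the helper data were selected on).
#' @param helper [select_reliable_features()] output.
#' @param model The population model.
#' @param gamma Optional normalized Hamming-distance threshold to store.
#' @return A `key_template`.
#' @export
generate_template <- function(features, helper, model, gamma = NA_real_) {
  stopifnot(inherits(helper, "helper_data"), inherits(model, "population_model"))
  X <- feature_matrix(features)
  mu_s <- colMeans(X)
  sel <- helper$pair_ids
  if (length(sel) == 0L) {
    warn(sprintf("subject %s: empty selection, empty key template", helper$subject_id))
    return(structure(list(subject_id = helper$subject_id,
                          context_id = helper$context_id,
                          bits = integer(0), gamma = gamma,
                          pair_ids = sel, model_version = model$version),
                     class = "key_template"))
  }
  pr <- model$pairs[match(sel, model$pairs$pair_id), , drop = FALSE]
  d <- mu_s - model$mu_pop
  if (model$bits_per_feature == 2L) {
    mrg <- model$margin[match(sel, model$pairs$pair_id), , drop = FALSE]
    ok <- abs(d[pr$i]) > 0 & abs(d[pr$j]) > 0 &
      abs(d[pr$i]) >= mrg[, "m_x"] & abs(d[pr$j]) >= mrg[, "m_y"]
  } else {
    mrg <- model$margin[match(sel, model$pairs$pair_id), , drop = FALSE]
    ok <- abs(d[pr$i]) >= mrg[, "m_x"] & d[pr$i] != 0
  }
  if (!all(ok)) {
    abort(sprintf("subject %s: %d selected pair(s) are strict-undecidable; helper data and model are inconsistent",
                  helper$subject_id, sum(!ok)))
  }
  bits <- key_bits_matrix(matrix(mu_s, nrow = 1L), helper, model)[1L, ]
  structure(list(subject_id = helper$subject_id, context_id = helper$context_id,
                 bits = as.integer(bits), gamma = gamma, pair_ids = sel,
                 model_version = model$version),
            class = "key_template")
}

#' @export
print.key_template <- function(x, ...) {
  cat(sprintf("<key_template> subject=%s context=%s: %d bits, gamma=%s\n",
              x$subject_id, x$context_id, length(x$bits),
              ifelse(is.na(x$gamma), "uncalibrated", format(x$gamma))))
  invisible(x)
}

#' Regenerate a key from freshly presented trials
#'
#' Fits the per-feature mean of the presented trials and sign-encodes every
#' selected pair against the stored population centre (quadrant code, margins
#' ignored), in the same bit order as the template.
#'
#' @param features Trial feature tibble of the presented samples (>= 1 row).
#' @param helper The claimed subject's helper data.
#' @param model The population model the helper refers to.
#' @return A `bit_key`.
#' @export
regenerate_key <- function(features, helper, model) {
  stopifnot(inherits(helper, "helper_data"), inherits(model, "population_model"))
  if (nrow(features) == 0L) abort("no samples presented")
  if (!identical(feature_cols(features), model$feature_names)) {
    abort("feature columns do not match the population model")
  }
  mu <- colMeans(feature_matrix(features))
  bits <- key_bits_matrix(matrix(mu, nrow = 1L), helper, model)[1L, ]
  new_bit_key(bits, helper$subject_id)
}

#' Compare a regenerated key against a template
#'
#' The key is valid iff its normalized Hamming distance to the template is at
#' most the template's threshold `gamma` (boundary inclusive).
#'
#' @param key A `bit_key` (or integer 0/1 vector).
#' @param template A `key_template` with a calibrated `gamma`.
#' @param gamma Optional override of the stored threshold.
#' @return A list with `valid` (logical) and `distance` (normalized Hamming
#'   distance).
#' @export
authenticate <- function(key, template, gamma = NULL) {
  bits <- if (inherits(key, "bit_key")) key$bits else as.integer(key)
  if (length(bits) != length(template$bits)) {
    abort(sprintf("key length %d does not match template length %d (wrong helper data or model version?)",
                  length(bits), length(template$bits)))
  }
  g <- if (!is.null(gamma)) gamma else template$gamma
  if (is.na(g)) abort("template has no calibrated gamma; pass `gamma` explicitly")
  d <- if (length(bits) == 0L) 0 else mean(bits != template$bits)
  list(valid = d <= g + 1e-12, distance = d)
}

# normalized Hamming distances of key rows against template bits
hd_to_template <- function(K, template_bits) {
  L <- length(template_bits)
  if (L == 0L) return(rep(0, nrow(K)))
  rowMeans(K != matrix(template_bits, nrow(K), L, byrow = TRUE))
}

#' Calibrate the per-subject similarity threshold
#'
#' Scans the grid of achievable normalized Hamming distances
#' `{0, 1/L, ..., 1}` on validation keys and picks the threshold `gamma`
#' maximizing authentication accuracy minus false acceptance rate; among
#' maximizers the one with the highest accuracy wins, and remaining ties go to
#' the smallest (strictest) `gamma`. With no impostor keys the objective
#' reduces to accuracy and the calibrated threshold is the largest genuine
#' distance.
#'
#' @param genuine_keys List of `bit_key`s regenerated from the subject's own
#'   validation samples (>= 1).
#' @param impostor_keys List of `bit_key`s from other subjects (possibly
#'   empty), regenerated against this subject's helper data.
#' @param template The subject's `key_template`.
#' @return The calibrated `gamma` (normalized distance in \[0, 1\]).
#' @export
calibrate_gamma <- function(genuine_keys, impostor_keys, template) {
  if (length(genuine_keys) == 0L) abort("need at least one genuine validation key")
  as_mat <- function(keys) {
    do.call(rbind, lapply(keys, function(k) if (inherits(k, "bit_key")) k$bits else as.integer(k)))
  }
  L <- length(template$bits)
  if (L == 0L) return(0)
  gd <- hd_to_template(as_mat(genuine_keys), template$bits)
  id <- if (length(impostor_keys) > 0L) hd_to_template(as_mat(impostor_keys), template$bits) else numeric(0)
  calibrate_grid(gd, id, L)
}

# grid search over achievable normalized distances; see calibrate_gamma()
calibrate_grid <- function(genuine_dist, impostor_dist, L) {
  grid <- (0:L) / L
  eps <- 1e-12
  acc <- vapply(grid, function(g) mean(genuine_dist <= g + eps), numeric(1))
  far <- if (length(impostor_dist) > 0L) {
    vapply(grid, function(g) mean(impostor_dist <= g + eps), numeric(1))
  } else rep(0, length(grid))
  obj <- acc - far
  best <- which(obj >= max(obj) - eps)
  best <- best[acc[best] >= max(acc[best]) - eps]
  grid[best[1L]]
}
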
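# Internal: per-subject diagonal-Gaussian profiles from a trial feature table.
# Returns subject labels plus k x F matrices of means and ML standard
# deviations, and the per-subject training matrices.
fit_profiles <- function(features) {
  if (!"subject_id" %in% names(features)) abort("features need a subject_id column")
  cols <- feature_cols(features)
  split_tbl <- split(features, features$subject_id)
  subjects <- names(split_tbl)
  mats <- lapply(split_tbl, function(tb) as.matrix(tb[cols]))
  small <- vapply(mats, nrow, integer(1)) < 2L
  if (any(small)) {
    abort(sprintf("subject(s) %s have fewer than 2 training trials",
                  paste(subjects[small], collapse = ", ")))
  }
  fits <- lapply(mats, fit_gaussian)
  list(
    subjects = subjects,
    mu = do.call(rbind, lapply(fits, `[[`, "mean")),
    sigma = do.call(rbind, lapply(fits, `[[`, "sd")),
    n = vapply(mats, nrow, integer(1)),
    matrices = mats,
    feature_names = cols
  )
}

#' Subject profile: per-feature Gaussian fit for one subject
#'
#' Convenience wrapper around [fit_gaussian()] for a single subject's training
#' trials: per-feature mean and maximum-likelihood standard deviation.
#'
#' @param features Trial feature tibble containing one subject.
#' @return A list with `subject_id`, `mean`, `sd` (named by feature) and
#'   `n_train`.
#' @export
subject_profile <- function(features) {
  sid <- unique(features$subject_id)
  if (length(sid) != 1L) abort("`features` must contain exactly one subject")
  fit <- fit_gaussian(feature_matrix(features))
  cols <- feature_cols(features)
  list(subject_id = sid, mean = setNames(fit$mean, cols),
       sd = setNames(fit$sd, cols), n_train = nrow(features))
}

#' Fit the population margin model
#'
#' The first registration step: pooled training trials of all subjects are
#' fitted per feature to an axis-aligned Gaussian (the population centre and
#' spread), and per feature pair the margins are derived from the worst-case
#' subject — the subject maximising `sigma_x^2 + sigma_y^2` on that pair —
#' via [compute_margin_2d()] (or [compute_margin_1d()] in the 1-bit case).
#' The gallery of enrolled subjects is the population; no external cohort is
#' used.
#'
#' Pairs whose pooled population spread falls below
#' `sigma_floor_scale * mean(sigma_pop)` on either axis are flagged unusable
#' and never selected.
#'
#' @param features Training trial feature tibble covering >= 2 subjects.
#' @param alpha Maximum allowable wrong-side probability mass per subject and
#'   axis, in (0, 0.5). Larger `alpha` shrinks the margins, admitting more
#'   feature pairs at the cost of per-bit reliability.
#' @param bits_per_feature 2 (feature pairs, default) or 1 (single features).
#' @param margin_convention Passed to [compute_margin_2d()].
#' @param sigma_floor_scale Relative degeneracy floor for population spreads.
#' @return An object of class `population_model`.
#' @export
build_population_model <- function(features, alpha = 0.3, bits_per_feature = 2,
                                   margin_convention = c("independent", "joint"),
                                   sigma_floor_scale = 1e-9) {
  margin_convention <- match.arg(margin_convention)
  if (!bits_per_feature %in% c(1L, 2L)) abort("`bits_per_feature` must be 1 or 2")
  prof <- fit_profiles(features)
  if (length(prof$subjects) < 2L) abort("population model needs at least 2 subjects")

  pooled <- fit_gaussian(feature_matrix(features))
  nf <- length(prof$feature_names)
  V <- prof$sigma^2                                   # k x F subject variances

  if (bits_per_feature == 2L) {
    pairs <- pair_features(nf)
    tot <- V[, pairs$i, drop = FALSE] + V[, pairs$j, drop = FALSE]  # k x P
    worst <- max.col(t(tot), ties.method = "first")
    sd_x <- prof$sigma[cbind(worst, pairs$i)]
    sd_y <- prof$sigma[cbind(worst, pairs$j)]
    if (margin_convention == "independent") {
      u <- qnorm(1 - alpha)
    } else {
      if (alpha < 0.25) abort("joint margin convention is infeasible for alpha < 0.25")
      u <- qnorm(0.5 + sqrt(0.5 - alpha))
    }
    margin <- cbind(m_x = sd_x * u, m_y = sd_y * u)
    floor_val <- sigma_floor_scale * mean(pooled$sd)
    usable <- pooled$sd[pairs$i] > floor_val & pooled$sd[pairs$j] > floor_val &
      sd_x > 0 & sd_y > 0
  } else {
    pairs <- tibble::tibble(pair_id = seq_len(nf), i = seq_len(nf))
    worst <- max.col(t(V), ties.method = "first")
    sd_x <- prof$sigma[cbind(worst, pairs$i)]
    margin <- cbind(m_x = sd_x * qnorm(1 - alpha))
    floor_val <- sigma_floor_scale * mean(pooled$sd)
    usable <- pooled$sd[pairs$i] > floor_val & sd_x > 0
  }

  structure(
    list(
      feature_names = prof$feature_names,
      bits_per_feature = as.integer(bits_per_feature),
      alpha = alpha,
      margin_convention = margin_convention,
      mu_pop = setNames(pooled$mean, prof$feature_names),
      sigma_pop = setNames(pooled$sd, prof$feature_names),
      pairs = pairs,
      margin = margin,
      worst_subject = prof$subjects[worst],
      usable = usable,
      sigma_floor = floor_val,
      subjects = prof$subjects,
      version = 1L
    ),
    class = "population_model"
  )
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf("<population_model> %d features, %d pair(s), %d-bit codes, alpha=%g (%s margins)\n",
              length(x$feature_names), nrow(x$pairs), x$bits_per_feature,
              x$alpha, x$margin_convention))
  cat(sprintf("  fitted on %d subjects; %d usable pair(s)\n",
              length(x$subjects), sum(x$usable)))
  invisible(x)
}

#' @rdname tidy.population_model
#' @export
tidy.population_model <- function(x, ...) {
  out <- x$pairs
  out$center_x <- unname(x$mu_pop[out$i])
  out$margin_x <- x$margin[, "m_x"]
  if (x$bits_per_feature == 2L) {
    out$center_y <- unname(x$mu_pop[out$j])
    out$margin_y <- x$margin[, "m_y"]
  }
  out$worst_subject <- x$worst_subject
  out$usable <- x$usable
  tibble::as_tibble(out)
}

#' Tidy a population margin model
#'
#' One row per feature pair with the population centre, per-axis margins, the
#' worst-case subject used for the margin, and the usability flag.
#'
#' @param x A `population_model`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy.population_model
NULL
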
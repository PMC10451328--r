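# Internal: average consecutive chunks of n_auth rows (one authentication
# presentation = n_auth trials); a trailing partial chunk is dropped.
chunk_means <- function(X, n_auth) {
  if (n_auth <= 1L) return(X)
  k <- nrow(X) %/% n_auth
  if (k == 0L) abort("fewer samples than `n_auth_trials`")
  grp <- rep(seq_len(k), each = n_auth)
  rowsum(X[seq_len(k * n_auth), , drop = FALSE], grp) / n_auth
}

#' Split trials into train/validation/test partitions
#'
#' Adds a `split` column. When a `session_day` column is present, whole
#' sessions are assigned to partitions (mirroring day-wise protocols);
#' otherwise trials are assigned at random within each subject/context group.
#' Fractions must be positive for train and sum to 1.
#'
#' @param features Trial feature tibble.
#' @param train,validation,test Fractions summing to 1 (default 0.8/0.1/0.1).
#' @param seed Integer seed for the random assignment.
#' @return The input tibble with a `split` factor column.
#' @export
split_trials <- function(features, train = 0.8, validation = 0.1, test = 0.1,
                         seed = 1L) {
  fr <- c(train, validation, test)
  if (any(fr < 0) || train <= 0 || abs(sum(fr) - 1) > 1e-8) {
    abort("split fractions must be non-negative, train > 0, and sum to 1")
  }
  grp_cols <- intersect(c("subject_id", "context_id"), names(features))
  by_day <- "session_day" %in% names(features) &&
    length(unique(features$session_day)) > 1L
  set.seed(seed)
  assign_units <- function(n) {
    n_tr <- max(1L, round(train * n))
    n_va <- round(validation * n)
    n_te <- n - n_tr - n_va
    if (n_te < 0) { n_va <- n_va + n_te; n_te <- 0L }
    sample(rep(c("train", "validation", "test"), times = c(n_tr, n_va, n_te)))
  }
  features |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp_cols))) |>
    dplyr::group_modify(function(tb, key) {
      if (by_day) {
        days <- sort(unique(tb$session_day))
        lab <- setNames(assign_units(length(days)), days)
        tb$split <- unname(lab[as.character(tb$session_day)])
      } else {
        tb$split <- assign_units(nrow(tb))
      }
      tb
    }) |>
    dplyr::ungroup()
}

#' Register a cohort: population model, helper data, templates, thresholds
#'
#' Runs the full registration workflow on a training table of >= 2 subjects:
#' fits the population margin model, selects each subject's reliable feature
#' pairs, strict-encodes the key templates, and — when a validation table is
#' supplied — calibrates each subject's similarity threshold `gamma` by
#' regenerating keys from validation trials (the subject's own trials as
#' genuine presentations, all other subjects' trials as impostor
#' presentations).
#'
#' @param train Training trial feature tibble (>= 2 subjects).
#' @param validation Optional validation tibble with the same columns; without
#'   it templates carry `gamma = default_gamma`.
#' @param alpha,bits_per_feature,margin_convention,sigma_floor_scale Passed to
#'   [build_population_model()].
#' @param beta Minimum valid-sample proportion for pair selection.
#' @param n_auth_trials Trials averaged into one authentication presentation
#'   (default 5, i.e. a 10-s session at the canonical 2-s trial length: the
#'   authentication step fits the subject's statistics on a short batch, not
#'   a single trial).
#' @param default_gamma Threshold stored when no validation data are given.
#' @return An object of class `nk_enrollment` bundling the model, per-subject
#'   helper data, templates and summary.
#' @export
enroll_cohort <- function(train, validation = NULL, alpha = 0.3, beta = 0.8,
                          bits_per_feature = 2,
                          margin_convention = c("independent", "joint"),
                          sigma_floor_scale = 1e-9, n_auth_trials = 5L,
                          default_gamma = 0) {
  margin_convention <- match.arg(margin_convention)
  model <- build_population_model(train, alpha = alpha,
                                  bits_per_feature = bits_per_feature,
                                  margin_convention = margin_convention,
                                  sigma_floor_scale = sigma_floor_scale)
  cols <- model$feature_names
  train_split <- split(train, train$subject_id)
  subjects <- names(train_split)

  helpers <- list(); templates <- list()
  means <- matrix(NA_real_, length(subjects), length(cols),
                  dimnames = list(subjects, cols))
  for (s in subjects) {
    tb <- train_split[[s]]
    X <- as.matrix(tb[cols])
    fit <- fit_gaussian(X)
    means[s, ] <- fit$mean
    ids <- select_pairs_internal(fit$mean, X, model, beta)
    helpers[[s]] <- structure(
      list(subject_id = s,
           context_id = if ("context_id" %in% names(tb)) unique(tb$context_id)[1] else NA_character_,
           pair_ids = sort(ids), beta = beta, model_version = model$version),
      class = "helper_data")
    templates[[s]] <- generate_template(tb, helpers[[s]], model, gamma = default_gamma)
  }

  if (!is.null(validation)) {
    val_split <- split(validation, validation$subject_id)
    val_keys <- lapply(subjects, function(s) {
      lapply(val_split, function(tb) {
        key_bits_matrix(chunk_means(as.matrix(tb[cols]), n_auth_trials),
                        helpers[[s]], model)
      })
    })
    names(val_keys) <- subjects
    for (s in subjects) {
      tmpl <- templates[[s]]
      L <- length(tmpl$bits)
      if (L == 0L) { templates[[s]]$gamma <- 0; next }
      gd <- hd_to_template(val_keys[[s]][[s]], tmpl$bits)
      others <- setdiff(names(val_keys[[s]]), s)
      id <- if (length(others)) {
        hd_to_template(do.call(rbind, val_keys[[s]][others]), tmpl$bits)
      } else numeric(0)
      templates[[s]]$gamma <- calibrate_grid(gd, id, L)
    }
  }

  structure(
    list(model = model, helpers = helpers, templates = templates,
         subject_means = means, subjects = subjects,
         beta = beta, n_auth_trials = as.integer(n_auth_trials)),
    class = "nk_enrollment"
  )
}

#' @export
print.nk_enrollment <- function(x, ...) {
  kl <- vapply(x$templates, function(t) length(t$bits), integer(1))
  cat(sprintf("<nk_enrollment> %d subject(s), alpha=%g beta=%g, %d-bit codes\n",
              length(x$subjects), x$model$alpha, x$beta, x$model$bits_per_feature))
  cat(sprintf("  key lengths: %s bits (mean %.0f)\n",
              paste(kl, collapse = "/"), mean(kl)))
  invisible(x)
}

#' @export
tidy.nk_enrollment <- function(x, ...) {
  tibble::tibble(
    subject_id = x$subjects,
    n_selected = vapply(x$helpers, function(h) length(h$pair_ids), integer(1)),
    key_length = vapply(x$templates, function(t) length(t$bits), integer(1)),
    gamma = vapply(x$templates, function(t) t$gamma, numeric(1))
  )
}

#' @export
glance.nk_enrollment <- function(x, ...) {
  tt <- tidy(x)
  tibble::tibble(
    n_subjects = nrow(tt),
    n_pairs = nrow(x$model$pairs),
    alpha = x$model$alpha,
    beta = x$beta,
    bits_per_feature = x$model$bits_per_feature,
    mean_key_length = mean(tt$key_length),
    average_entropy = average_entropy(x)
  )
}

#' Evaluate an enrollment on held-out trials
#'
#' Regenerates one key per authentication presentation from the test trials
#' and reports, per subject, the authentication accuracy (fraction of the
#' subject's own keys accepted by its template), the pooled false acceptance
#' rate over all other subjects' presentations, the key length and the
#' threshold `gamma`.
#'
#' @param enrollment An [enroll_cohort()] object.
#' @param test Held-out trial feature tibble covering the enrolled subjects.
#' @param n_auth_trials Trials per presentation; defaults to the enrollment
#'   setting.
#' @return A tibble (class `nk_evaluation`) with one row per subject and an
#'   `average_entropy` attribute; see [glance.nk_evaluation()].
#' @export
evaluate_enrollment <- function(enrollment, test,
                                n_auth_trials = enrollment$n_auth_trials) {
  stopifnot(inherits(enrollment, "nk_enrollment"))
  cols <- enrollment$model$feature_names
  test_split <- split(test, test$subject_id)
  subjects <- intersect(enrollment$subjects, names(test_split))
  if (length(subjects) == 0L) abort("test set contains none of the enrolled subjects")

  rows <- lapply(subjects, function(s) {
    tmpl <- enrollment$templates[[s]]
    L <- length(tmpl$bits)
    keys_of <- function(sid) {
      key_bits_matrix(chunk_means(as.matrix(test_split[[sid]][cols]), n_auth_trials),
                      enrollment$helpers[[s]], enrollment$model)
    }
    if (L == 0L) {
      return(tibble::tibble(subject_id = s, accuracy = NA_real_, far = NA_real_,
                            key_length = 0L, gamma = tmpl$gamma,
                            n_genuine = 0L, n_impostor = 0L))
    }
    gd <- hd_to_template(keys_of(s), tmpl$bits)
    others <- setdiff(subjects, s)
    id <- if (length(others)) {
      unlist(lapply(others, function(o) hd_to_template(keys_of(o), tmpl$bits)))
    } else numeric(0)
    eps <- 1e-12
    tibble::tibble(
      subject_id = s,
      accuracy = mean(gd <= tmpl$gamma + eps),
      far = if (length(id)) mean(id <= tmpl$gamma + eps) else NA_real_,
      key_length = L,
      gamma = tmpl$gamma,
      n_genuine = length(gd),
      n_impostor = length(id)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "average_entropy") <- average_entropy(enrollment)
  class(out) <- c("nk_evaluation", class(out))
  out
}

#' @rdname evaluate_enrollment
#' @param x An `nk_evaluation` tibble.
#' @param ... Unused.
#' @export
glance.nk_evaluation <- function(x, ...) {
  tibble::tibble(
    n_subjects = nrow(x),
    mean_accuracy = mean(x$accuracy, na.rm = TRUE),
    mean_far = mean(x$far, na.rm = TRUE),
    pooled_far = sum(x$far * x$n_impostor, na.rm = TRUE) /
      sum(x$n_impostor[!is.na(x$far)]),
    mean_key_length = mean(x$key_length),
    average_entropy = attr(x, "average_entropy")
  )
}

#' Cross-context false acceptance (revocability check)
#'
#' Measures whether a template enrolled in one behaviour/context accepts keys
#' derived from the same subjects recorded in *other* contexts: other-context
#' trials are regenerated against this context's helper data and compared to
#' this context's templates at the calibrated thresholds. Low values mean a
#' revoked (re-enrolled under a new behaviour) key is independent of the old
#' one.
#'
#' @param enrollment Enrollment of the reference context.
#' @param other_features Trial feature tibble from other context(s) of the
#'   same subjects.
#' @param n_auth_trials Trials per presentation.
#' @return Pooled fraction of other-context presentations accepted, with a
#'   per-subject breakdown in the `"by_subject"` attribute.
#' @export
cross_context_far <- function(enrollment, other_features,
                              n_auth_trials = enrollment$n_auth_trials) {
  stopifnot(inherits(enrollment, "nk_enrollment"))
  cols <- enrollment$model$feature_names
  subjects <- intersect(enrollment$subjects, unique(other_features$subject_id))
  if (length(subjects) == 0L) abort("no other-context data for any enrolled subject")
  eps <- 1e-12
  acc <- 0L; tot <- 0L
  by_subj <- numeric(0)
  for (s in subjects) {
    tmpl <- enrollment$templates[[s]]
    if (length(tmpl$bits) == 0L) next
    tb <- other_features[other_features$subject_id == s, , drop = FALSE]
    K <- key_bits_matrix(chunk_means(as.matrix(tb[cols]), n_auth_trials),
                         enrollment$helpers[[s]], enrollment$model)
    d <- hd_to_template(K, tmpl$bits)
    ok <- sum(d <= tmpl$gamma + eps)
    acc <- acc + ok; tot <- tot + length(d)
    by_subj[s] <- ok / length(d)
  }
  if (tot == 0L) abort("no usable other-context presentations")
  structure(acc / tot, by_subject = by_subj)
}
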
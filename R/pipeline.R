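# Resolve a run configuration: a YAML file path or a nested list. Flags in
# `...` override config entries at the top level.
resolve_config <- function(config, ...) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML file path")
  utils::modifyList(config, rlang::list2(...))
}

default_params <- function(p) {
  utils::modifyList(list(alpha = 0.3, beta = 0.8, bits_per_feature = 2,
                         margin_convention = "independent", n_auth_trials = 5),
                    p %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_run_features <- function(config) {
  if (!is.null(config$features)) {
    dplyr::bind_rows(lapply(config$features, read_features))
  } else if (!is.null(config$simulate)) {
    sim <- config$simulate
    do.call(simulate_feature_cohort,
            utils::modifyList(sim, list(seed = sim$seed %||% config$seed %||% 1L)))
  } else {
    abort("config needs either `features` (file paths) or a `simulate` spec")
  }
}

#' Run the registration pipeline
#'
#' Loads (or simulates) trial features per the run configuration, splits them
#' into train/validation/test, registers the cohort, and writes every
#' artifact under `out_dir`: the population model, per-subject helper data
#' and key templates (JSON), the split feature table, a per-subject summary
#' and a manifest. The per-subject key lengths are logged to stderr.
#'
#' @param config A nested list or YAML file path with entries `out_dir`,
#'   `seed`, `parameters` (`alpha`, `beta`, `bits_per_feature`,
#'   `margin_convention`, `n_auth_trials`), `split` (`train`, `validation`,
#'   `test` fractions), and either `features` (vector of TSV paths) or
#'   `simulate` (arguments to [simulate_feature_cohort()]).
#' @param ... Top-level config overrides.
#' @return The `nk_enrollment`, invisibly.
#' @export
run_register <- function(config, ...) {
  config <- resolve_config(config, ...)
  out_dir <- config$out_dir %||% abort("config needs `out_dir`")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- default_params(config$parameters)
  sp <- utils::modifyList(list(train = 0.8, validation = 0.1, test = 0.1),
                          config$split %||% list())
  seed <- config$seed %||% 1L

  features <- load_run_features(config)
  if (!"context_id" %in% names(features)) features$context_id <- "c01"
  if (length(unique(features$subject_id)) < 2L) {
    abort("registration needs training features for at least 2 subjects")
  }
  if (!"split" %in% names(features)) {
    features <- split_trials(features, sp$train, sp$validation, sp$test, seed = seed)
  }
  write_features(features, file.path(out_dir, "features_split.tsv"))

  contexts <- unique(features$context_id)
  manifest <- list(format = "neurokey_run", seed = seed, parameters = p,
                   split = sp, contexts = contexts, files = list())
  first_enr <- NULL
  for (ctx in contexts) {
    fc <- features[features$context_id == ctx, , drop = FALSE]
    enr <- enroll_cohort(fc[fc$split == "train", , drop = FALSE],
                         validation = if (any(fc$split == "validation"))
                           fc[fc$split == "validation", , drop = FALSE],
                         alpha = p$alpha, beta = p$beta,
                         bits_per_feature = p$bits_per_feature,
                         margin_convention = p$margin_convention,
                         n_auth_trials = p$n_auth_trials)
    tag <- function(stem, s = NULL) {
      file.path(out_dir, paste0(stem, "_", ctx, if (!is.null(s)) paste0("_", s), ".json"))
    }
    write_population_model(enr$model, tag("population_model"))
    for (s in enr$subjects) {
      write_helper_data(enr$helpers[[s]], tag("helper", s))
      write_key_template(enr$templates[[s]], tag("template", s))
    }
    tt <- tidy(enr)
    utils::write.table(tt, file.path(out_dir, paste0("registration_", ctx, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    message(sprintf("context %s: key lengths %s", ctx,
                    paste(sprintf("%s=%d", tt$subject_id, tt$key_length), collapse = " ")))
    if (all(tt$key_length == 0L)) {
      warn(sprintf("context %s: no subject obtained a non-empty key", ctx))
    }
    manifest$files[[ctx]] <- list(model = tag("population_model"))
    if (ctx == contexts[1]) first_enr <- enr
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(first_enr)
}

# Rebuild an enrollment (minus calibration data) from registration artifacts.
load_enrollment <- function(out_dir, ctx, features_train) {
  model <- read_population_model(file.path(out_dir, sprintf("population_model_%s.json", ctx)))
  subjects <- model$subjects
  helpers <- lapply(subjects, function(s)
    read_helper_data(file.path(out_dir, sprintf("helper_%s_%s.json", ctx, s))))
  templates <- lapply(subjects, function(s)
    read_key_template(file.path(out_dir, sprintf("template_%s_%s.json", ctx, s))))
  names(helpers) <- names(templates) <- subjects
  cols <- model$feature_names
  means <- t(vapply(split(features_train, features_train$subject_id)[subjects],
                    function(tb) colMeans(as.matrix(tb[cols])), numeric(length(cols))))
  structure(list(model = model, helpers = helpers, templates = templates,
                 subject_means = means, subjects = subjects,
                 beta = helpers[[1]]$beta, n_auth_trials = 5L),
            class = "nk_enrollment")
}

#' Run the evaluation pipeline
#'
#' Loads the artifacts written by [run_register()], regenerates keys from the
#' held-out test trials, and writes a per-subject report (accuracy, false
#' acceptance rate, key length, gamma) plus the population average
#' min-entropy, as TSV and JSON. With more than one context the cross-context
#' acceptance matrix (revocability) is also reported.
#'
#' @param config The same configuration passed to [run_register()] (needs
#'   `out_dir`).
#' @param ... Top-level config overrides.
#' @return A list of per-context `nk_evaluation` tibbles, invisibly.
#' @export
run_evaluate <- function(config, ...) {
  config <- resolve_config(config, ...)
  out_dir <- config$out_dir %||% abort("config needs `out_dir`")
  split_path <- file.path(out_dir, "features_split.tsv")
  if (!file.exists(split_path)) {
    abort(sprintf("no registration artifacts under %s (missing %s)", out_dir, split_path))
  }
  features <- read_features(split_path)
  p <- default_params(config$parameters)
  contexts <- unique(features$context_id)
  reports <- list()
  for (ctx in contexts) {
    fc <- features[features$context_id == ctx, , drop = FALSE]
    enr <- load_enrollment(out_dir, ctx, fc[fc$split == "train", , drop = FALSE])
    enr$n_auth_trials <- p$n_auth_trials
    rep_tbl <- evaluate_enrollment(enr, fc[fc$split == "test", , drop = FALSE])
    utils::write.table(rep_tbl, file.path(out_dir, paste0("report_", ctx, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(per_subject = rep_tbl, summary = glance(rep_tbl)),
      file.path(out_dir, paste0("report_", ctx, ".json")),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    reports[[ctx]] <- rep_tbl
  }
  if (length(contexts) > 1L) {
    cross <- purrr::map_dfr(contexts, function(a) {
      fa <- features[features$context_id == a, , drop = FALSE]
      enr <- load_enrollment(out_dir, a, fa[fa$split == "train", , drop = FALSE])
      purrr::map_dfr(setdiff(contexts, a), function(b) {
        fb <- features[features$context_id == b & features$split == "test", , drop = FALSE]
        tibble::tibble(template_context = a, probe_context = b,
                       far = as.numeric(cross_context_far(enr, fb)))
      })
    })
    utils::write.table(cross, file.path(out_dir, "cross_context_far.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    attr(reports, "cross_context") <- cross
  }
  invisible(reports)
}

#' Sweep the overlap parameter alpha
#'
#' Re-registers a fixed cohort at each `alpha` and evaluates it, returning
#' per-alpha mean accuracy, pooled FAR, mean key length and average entropy.
#' Because margins shrink monotonically as `alpha` grows, the selected pair
#' sets are nested and key length is non-decreasing in `alpha`.
#'
#' @param features A trial feature tibble with a `split` column (see
#'   [split_trials()]).
#' @param alphas Vector of overlap values in (0, 0.5).
#' @param beta,bits_per_feature,n_auth_trials Registration settings.
#' @return A tibble of class `nk_sweep` (one row per alpha).
#' @export
sweep_alpha <- function(features, alphas = seq(0.20, 0.45, by = 0.05),
                        beta = 0.8, bits_per_feature = 2, n_auth_trials = 5L) {
  if (!"split" %in% names(features)) abort("features need a `split` column; see split_trials()")
  tr <- features[features$split == "train", , drop = FALSE]
  va <- features[features$split == "validation", , drop = FALSE]
  te <- features[features$split == "test", , drop = FALSE]
  out <- purrr::map_dfr(alphas, function(a) {
    enr <- enroll_cohort(tr, validation = if (nrow(va)) va, alpha = a, beta = beta,
                         bits_per_feature = bits_per_feature,
                         n_auth_trials = n_auth_trials)
    ev <- evaluate_enrollment(enr, te)
    g <- glance(ev)
    tibble::tibble(alpha = a, mean_accuracy = g$mean_accuracy,
                   pooled_far = g$pooled_far,
                   mean_key_length = g$mean_key_length,
                   average_entropy = g$average_entropy)
  })
  class(out) <- c("nk_sweep", class(out))
  attr(out, "parameter") <- "alpha"
  out
}

#' Sweep the similarity threshold gamma
#'
#' Evaluates an existing enrollment over a grid of thresholds, pooling
#' genuine and impostor distances across subjects. Both accuracy and FAR are
#' non-decreasing in `gamma`.
#'
#' @param enrollment An [enroll_cohort()] object.
#' @param test Held-out trial feature tibble.
#' @param gammas Threshold grid in \[0, 1\].
#' @return A tibble of class `nk_sweep` with columns `gamma`,
#'   `mean_accuracy`, `pooled_far`.
#' @export
sweep_gamma <- function(enrollment, test, gammas = seq(0, 0.5, by = 0.05)) {
  cols <- enrollment$model$feature_names
  test_split <- split(test, test$subject_id)
  subjects <- intersect(enrollment$subjects, names(test_split))
  gd <- list(); id <- list()
  for (s in subjects) {
    tmpl <- enrollment$templates[[s]]
    if (length(tmpl$bits) == 0L) next
    keys_of <- function(sid) {
      key_bits_matrix(chunk_means(as.matrix(test_split[[sid]][cols]),
                                  enrollment$n_auth_trials),
                      enrollment$helpers[[s]], enrollment$model)
    }
    gd[[s]] <- hd_to_template(keys_of(s), tmpl$bits)
    id[[s]] <- unlist(lapply(setdiff(subjects, s),
                             function(o) hd_to_template(keys_of(o), tmpl$bits)))
  }
  gd <- unlist(gd); id <- unlist(id)
  eps <- 1e-12
  out <- tibble::tibble(
    gamma = gammas,
    mean_accuracy = vapply(gammas, function(g) mean(gd <= g + eps), numeric(1)),
    pooled_far = vapply(gammas, function(g) mean(id <= g + eps), numeric(1))
  )
  class(out) <- c("nk_sweep", class(out))
  attr(out, "parameter") <- "gamma"
  out
}
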
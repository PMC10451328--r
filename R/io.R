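# --- trial feature tables -------------------------------------------------

#' Read / write trial feature tables
#'
#' Tab-delimited text with a header row; metadata columns (`subject_id`,
#' `context_id`, `session_day`, `trial`, `split`) are kept as-is and every
#' other column is a feature.
#'
#' @param features Trial feature tibble.
#' @param path File path.
#' @return `read_features()` returns a tibble; `write_features()` returns
#'   `path` invisibly.
#' @export
write_features <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) abort(sprintf("feature file not found: %s", path))
  tibble::as_tibble(utils::read.delim(path, check.names = FALSE))
}

#' Read behaviour annotations
#'
#' Tab-delimited file with columns `label`, `start_sample`, `end_sample`
#' (0-based, half-open intervals).
#'
#' @param path File path.
#' @return A tibble suitable for [signal_record()]'s `annotations` field.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) abort(sprintf("annotation file not found: %s", path))
  tb <- tibble::as_tibble(utils::read.delim(path))
  req <- c("label", "start_sample", "end_sample")
  if (!all(req %in% names(tb))) abort("annotations need columns label, start_sample, end_sample")
  tb
}

# --- bit strings ----------------------------------------------------------

bits_to_hex <- function(bits) {
  if (length(bits) == 0L) return("")
  pad <- (-length(bits)) %% 4L
  b <- c(as.integer(bits), rep(0L, pad))
  nib <- matrix(b, nrow = 4L)
  vals <- 8L * nib[1, ] + 4L * nib[2, ] + 2L * nib[3, ] + nib[4, ]
  chars <- strsplit("0123456789abcdef", "")[[1]]
  paste(chars[vals + 1L], collapse = "")
}

hex_to_bits <- function(hex, n_bits) {
  if (n_bits == 0L) return(integer(0))
  vals <- match(strsplit(tolower(hex), "")[[1]],
                strsplit("0123456789abcdef", "")[[1]]) - 1L
  bits <- as.vector(vapply(vals, function(v) {
    as.integer(intToBits(v)[4:1] != 0)
  }, integer(4)))
  bits[seq_len(n_bits)]
}

# --- JSON artifacts -------------------------------------------------------

#' Serialize registration artifacts as JSON
#'
#' The population model and helper data are non-secret by design and are
#' stored as versioned JSON documents; key templates store the bit string in
#' hex together with its bit length. `write_key()` exports a raw key as a
#' plain `0`/`1` text string.
#'
#' @param model,helper,template,key Objects to serialize.
#' @param path File path.
#' @return Readers return the reconstructed object; writers return `path`
#'   invisibly.
#' @name artifact_io
NULL

#' @rdname artifact_io
#' @export
write_population_model <- function(model, path) {
  stopifnot(inherits(model, "population_model"))
  doc <- list(
    format = "neurokey_population_model", version = model$version,
    bits_per_feature = model$bits_per_feature, alpha = model$alpha,
    margin_convention = model$margin_convention,
    feature_names = model$feature_names,
    mu_pop = unname(model$mu_pop), sigma_pop = unname(model$sigma_pop),
    pairs = as.list(model$pairs[c("pair_id", "i", "j")[c("pair_id", "i", "j") %in% names(model$pairs)]]),
    margin = as.data.frame(model$margin),
    worst_subject = model$worst_subject,
    usable = model$usable, sigma_floor = model$sigma_floor,
    subjects = model$subjects
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname artifact_io
#' @export
read_population_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "neurokey_population_model")) {
    abort(sprintf("%s is not a population model document", path))
  }
  structure(
    list(
      feature_names = doc$feature_names,
      bits_per_feature = as.integer(doc$bits_per_feature),
      alpha = doc$alpha, margin_convention = doc$margin_convention,
      mu_pop = setNames(doc$mu_pop, doc$feature_names),
      sigma_pop = setNames(doc$sigma_pop, doc$feature_names),
      pairs = tibble::as_tibble(doc$pairs),
      margin = as.matrix(doc$margin),
      worst_subject = doc$worst_subject,
      usable = doc$usable, sigma_floor = doc$sigma_floor,
      subjects = doc$subjects, version = as.integer(doc$version)
    ),
    class = "population_model"
  )
}

#' @rdname artifact_io
#' @export
write_helper_data <- function(helper, path) {
  stopifnot(inherits(helper, "helper_data"))
  jsonlite::write_json(
    list(format = "neurokey_helper_data", model_version = helper$model_version,
         subject_id = helper$subject_id, context_id = helper$context_id,
         beta = helper$beta, pair_ids = helper$pair_ids),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname artifact_io
#' @export
read_helper_data <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "neurokey_helper_data")) {
    abort(sprintf("%s is not a helper data document", path))
  }
  structure(list(subject_id = doc$subject_id, context_id = doc$context_id,
                 pair_ids = as.integer(doc$pair_ids), beta = doc$beta,
                 model_version = as.integer(doc$model_version)),
            class = "helper_data")
}

#' @rdname artifact_io
#' @export
write_key_template <- function(template, path) {
  stopifnot(inherits(template, "key_template"))
  jsonlite::write_json(
    list(format = "neurokey_key_template", model_version = template$model_version,
         subject_id = template$subject_id, context_id = template$context_id,
         gamma = template$gamma, n_bits = length(template$bits),
         bits_hex = bits_to_hex(template$bits),
         pair_ids = template$pair_ids),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname artifact_io
#' @export
read_key_template <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "neurokey_key_template")) {
    abort(sprintf("%s is not a key template document", path))
  }
  structure(list(subject_id = doc$subject_id, context_id = doc$context_id,
                 bits = hex_to_bits(doc$bits_hex, doc$n_bits),
                 gamma = doc$gamma,
                 pair_ids = as.integer(doc$pair_ids),
                 model_version = as.integer(doc$model_version)),
            class = "key_template")
}

#' @rdname artifact_io
#' @export
write_key <- function(key, path) {
  bits <- if (inherits(key, "bit_key")) key$bits else as.integer(key)
  writeLines(paste(bits, collapse = ""), path)
  invisible(path)
}

#' @rdname artifact_io
#' @export
read_key <- function(path, subject_id = NA_character_) {
  line <- trimws(readLines(path, n = 1L))
  new_bit_key(as.integer(strsplit(line, "")[[1]]), subject_id)
}
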
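test_that("selection rejects subjects at the centre and accepts well-separated ones", {
  model <- toy_model(2, margin = 1)

  at_centre <- toy_features(matrix(rnorm(40, 0, 0.1), 20, 2))
  expect_length(select_reliable_features(at_centre, model, beta = 0.5)$pair_ids, 0L)

  far <- toy_features(matrix(rnorm(40, 10, 0.1), 20, 2))
  expect_equal(select_reliable_features(far, model, beta = 0.9)$pair_ids, 1L)
})

test_that("the beta rule counts valid training samples strictly beyond the margins", {
  model <- toy_model(2, margin = 1)
  # subject mean well beyond the margin, but only 6 of 10 samples valid
  mat <- rbind(matrix(5, 6, 2), matrix(0.5, 4, 2))
  feats <- toy_features(mat)
  expect_length(select_reliable_features(feats, model, beta = 0.8)$pair_ids, 0L)
  expect_equal(select_reliable_features(feats, model, beta = 0.5)$pair_ids, 1L)
  # boundary counts as invalid: samples exactly on the margin never qualify
  on_margin <- toy_features(matrix(1, 11, 2))
  expect_length(select_reliable_features(on_margin, model, beta = 0.1)$pair_ids, 0L)
})

test_that("encode_feature implements the quadrant rules and the sign fallback", {
  expect_equal(encode_feature(c(-2, 3), c(0, 0), c(1, 1)), "00")
  expect_equal(encode_feature(c(2, 3), c(0, 0), c(1, 1)), "01")
  expect_equal(encode_feature(c(-2, -3), c(0, 0), c(1, 1)), "10")
  expect_equal(encode_feature(c(2, -3), c(0, 0), c(1, 1)), "11")
  expect_equal(encode_feature(c(0.5, 0.5), c(0, 0), c(1, 1), mode = "strict"),
               "undecidable")
  expect_equal(encode_feature(c(0.5, 0.5), c(0, 0), c(1, 1), mode = "sign"), "01")
})

test_that("the quadrant map is a Gray code", {
  codes <- matrix(c(
    encode_feature(c(-1, 1), c(0, 0), c(0, 0), "sign"),
    encode_feature(c(1, 1), c(0, 0), c(0, 0), "sign"),
    encode_feature(c(-1, -1), c(0, 0), c(0, 0), "sign"),
    encode_feature(c(1, -1), c(0, 0), c(0, 0), "sign")), 2, 2, byrow = TRUE)
  bit_diff <- function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  # horizontal neighbours
  expect_equal(bit_diff(codes[1, 1], codes[1, 2]), 1L)
  expect_equal(bit_diff(codes[2, 1], codes[2, 2]), 1L)
  # vertical neighbours
  expect_equal(bit_diff(codes[1, 1], codes[2, 1]), 1L)
  expect_equal(bit_diff(codes[1, 2], codes[2, 2]), 1L)
})

test_that("templates concatenate strict codes over selected pairs in helper order", {
  model <- toy_model(4, margin = 1)
  # f1=-2, f2=3 -> pair (1,2) codes 00 ; f3=2, f4=-3 -> pair (3,4) codes 11
  means <- c(-2, 3, 2, -3)
  feats <- toy_features(rbind(means, means))
  helper <- structure(list(subject_id = "s01", context_id = "c01",
                           pair_ids = c(1L, 6L), beta = 0.8, model_version = 1L),
                      class = "helper_data")
  tmpl <- generate_template(feats, helper, model)
  expect_equal(tmpl$bits, c(0L, 0L, 1L, 1L))
  expect_equal(length(tmpl$bits), 2L * length(helper$pair_ids))

  # brute-force cross-check: every selected pair re-encoded independently
  pr <- model$pairs
  manual <- unlist(lapply(helper$pair_ids, function(p) {
    code <- encode_feature(means[c(pr$i[p], pr$j[p])],
                           model$mu_pop[c(pr$i[p], pr$j[p])],
                           model$margin[p, ])
    as.integer(strsplit(code, "")[[1]])
  }))
  expect_equal(tmpl$bits, manual)
})

test_that("empty selections give an empty template with a warning", {
  model <- toy_model(2, margin = 1)
  helper <- structure(list(subject_id = "s01", context_id = "c01",
                           pair_ids = integer(0), beta = 0.8, model_version = 1L),
                      class = "helper_data")
  expect_warning(tmpl <- generate_template(toy_features(matrix(0, 3, 2)), helper, model),
                 "empty")
  expect_length(tmpl$bits, 0L)
})

test_that("undecidable selected pairs are an inconsistency error", {
  model <- toy_model(2, margin = 1)
  helper <- structure(list(subject_id = "s01", context_id = "c01",
                           pair_ids = 1L, beta = 0.8, model_version = 1L),
                      class = "helper_data")
  inside <- toy_features(matrix(0.2, 3, 2))
  expect_error(generate_template(inside, helper, model), "undecidable")
})

test_that("key regeneration reproduces and reflects as the quadrant map predicts", {
  model <- toy_model(4, margin = 1)
  means <- c(-2, 3, 2, -3)
  feats <- toy_features(rbind(means, means))
  helper <- structure(list(subject_id = "s01", context_id = "c01",
                           pair_ids = c(1L, 6L), beta = 0.8, model_version = 1L),
                      class = "helper_data")
  tmpl <- generate_template(feats, helper, model)

  # same samples -> same key
  key <- regenerate_key(feats, helper, model)
  expect_equal(key$bits, tmpl$bits)

  # small perturbation (noise << distance to centre) -> same key
  jit <- toy_features(rbind(means + 0.05, means - 0.05))
  expect_equal(regenerate_key(jit, helper, model)$bits, tmpl$bits)

  # reflection through the centre flips both axes, complementing every bit
  refl <- toy_features(rbind(-means, -means))
  expect_equal(regenerate_key(refl, helper, model)$bits, 1L - tmpl$bits)
})

test_that("authentication thresholds on normalized Hamming distance, boundary inclusive", {
  tmpl <- structure(list(subject_id = "s01", context_id = "c01",
                         bits = rep(0L, 10), gamma = 0.2, pair_ids = 1:5,
                         model_version = 1L), class = "key_template")
  same <- authenticate(rep(0L, 10), tmpl)
  expect_true(same$valid); expect_equal(same$distance, 0)

  three <- authenticate(c(rep(1L, 3), rep(0L, 7)), tmpl)
  expect_false(three$valid); expect_equal(three$distance, 0.3)

  two <- authenticate(c(rep(1L, 2), rep(0L, 8)), tmpl)
  expect_true(two$valid); expect_equal(two$distance, 0.2)

  expect_error(authenticate(rep(0L, 8), tmpl), "length")
})

test_that("gamma calibration follows the validation objective", {
  tmpl <- structure(list(subject_id = "s01", context_id = "c01",
                         bits = rep(0L, 10), gamma = NA_real_, pair_ids = 1:5,
                         model_version = 1L), class = "key_template")
  key_at <- function(d) c(rep(1L, round(10 * d)), rep(0L, 10 - round(10 * d)))

  # perfect separation -> strictest threshold
  expect_equal(calibrate_gamma(list(key_at(0), key_at(0)), list(key_at(0.5)), tmpl), 0)

  # inseparable: accuracy wins at gamma = genuine distance, objective 0
  tmpl20 <- structure(list(subject_id = "s01", context_id = "c01",
                           bits = rep(0L, 20), gamma = NA_real_, pair_ids = 1:10,
                           model_version = 1L), class = "key_template")
  key20 <- function(d) c(rep(1L, round(20 * d)), rep(0L, 20 - round(20 * d)))
  expect_equal(calibrate_gamma(list(key20(0.1)), list(key20(0.05)), tmpl20), 0.1)

  # no impostors -> smallest gamma reaching full accuracy = max genuine distance
  expect_equal(calibrate_gamma(list(key_at(0.1), key_at(0.3)), list(), tmpl), 0.3)

  expect_error(calibrate_gamma(list(), list(key_at(0.5)), tmpl), "genuine")
})

test_that("enrollment is deterministic and key length is twice the selection", {
  coh <- small_cohort(seed = 31)
  sp <- split_trials(coh, seed = 31)
  tr <- dplyr::filter(sp, split == "train")
  va <- dplyr::filter(sp, split == "validation")
  e1 <- enroll_cohort(tr, va)
  e2 <- enroll_cohort(tr, va)
  tt <- tidy(e1)
  expect_equal(tt$key_length, 2L * tt$n_selected)
  for (s in e1$subjects) {
    expect_identical(e1$templates[[s]]$bits, e2$templates[[s]]$bits)
    expect_identical(e1$helpers[[s]]$pair_ids, e2$helpers[[s]]$pair_ids)
  }
})

test_that("1-bit enrollment yields one bit per selected feature", {
  coh <- small_cohort(seed = 32)
  sp <- split_trials(coh, seed = 32)
  enr <- enroll_cohort(dplyr::filter(sp, split == "train"),
                       dplyr::filter(sp, split == "validation"),
                       bits_per_feature = 1)
  tt <- tidy(enr)
  expect_equal(tt$key_length, tt$n_selected)
  expect_gt(mean(tt$key_length), 0)
  ev <- evaluate_enrollment(enr, dplyr::filter(sp, split == "test"))
  expect_gte(min(ev$accuracy), 0.9)
})
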
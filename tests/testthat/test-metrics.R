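make_template <- function(bits, gamma) {
  structure(list(subject_id = "s01", context_id = "c01", bits = as.integer(bits),
                 gamma = gamma, pair_ids = seq_len(length(bits) / 2),
                 model_version = 1L), class = "key_template")
}

test_that("authentication accuracy is the fraction of valid keys", {
  tmpl <- make_template(rep(0L, 10), gamma = 0.2)
  flip <- function(k) { b <- rep(0L, 10); b[seq_len(k)] <- 1L; b }
  keys <- lapply(c(rep(0, 8), 5, 6), flip)   # 8 valid, 2 far away
  expect_equal(authentication_accuracy(keys, tmpl), 0.8)
  expect_equal(authentication_accuracy(lapply(1:10, function(i) rep(0L, 10)), tmpl), 1.0)
  expect_equal(authentication_accuracy(lapply(1:5, function(i) flip(1)), tmpl, gamma = 0), 0)
  expect_error(authentication_accuracy(list(), tmpl), "genuine")
})

test_that("false acceptance rate pools impostor samples across subjects", {
  tmpl <- make_template(rep(0L, 10), gamma = 0.2)
  far_keys <- lapply(1:10, function(i) rep(1L, 10))
  expect_equal(false_acceptance_rate(list(far_keys, far_keys), tmpl), 0)
  # 2 subjects x 10 samples, exactly one valid overall -> 1/20
  one_valid <- c(list(rep(0L, 10)), lapply(1:9, function(i) rep(1L, 10)))
  expect_equal(false_acceptance_rate(list(one_valid, far_keys), tmpl), 0.05)
  expect_error(false_acceptance_rate(list(), tmpl), "impostor")
})

test_that("random keys almost never match a long random template at gamma=0.25", {
  set.seed(41)
  L <- 1000
  tmpl <- make_template(sample(0:1, L, replace = TRUE), gamma = 0.25)
  keys <- lapply(1:200, function(i) sample(0:1, L, replace = TRUE))
  expect_equal(false_acceptance_rate(list(keys), tmpl), 0)
  # binomial oracle: acceptance probability is the lower tail at L/4 flips
  expect_lt(pbinom(L * 0.25, L, 0.5), 1e-50)
})

test_that("min-entropy matches the normalized most-probable-symbol formula", {
  expect_equal(min_entropy(c(1, 1, 1, 1) / 4), 1.0)
  expect_equal(min_entropy(c(10, 0, 0, 0)), 0.0)
  expect_equal(min_entropy(c(0.5, 0.25, 0.125, 0.125)), 0.5)  # -1/2 log2(1/2)
  expect_equal(min_entropy(c(1, 1), bits_per_feature = 1), 1.0)
  expect_equal(min_entropy(c(3, 1), bits_per_feature = 1), -log2(0.75))
  expect_error(min_entropy(c(0, 0, 0, 0)), "zero")
  expect_error(min_entropy(c(-1, 2, 0, 0)), "negative")
})

test_that("min-entropy is in [0,1], 1 iff uniform, 0 iff degenerate", {
  set.seed(42)
  for (i in 1:50) {
    p <- rgamma(4, 1); p <- p / sum(p)
    e <- min_entropy(p)
    expect_gte(e, 0); expect_lte(e, 1)
    if (e == 1) expect_equal(p, rep(0.25, 4))
    if (max(p) < 1) expect_gt(e, 0)
  }
})

test_that("average entropy means per-pair min-entropies over all pairs", {
  dist <- tibble::tibble(pair_id = 1:4,
                         n00 = c(1, 1, 4, 4), n01 = c(1, 1, 0, 0),
                         n10 = c(1, 1, 0, 0), n11 = c(1, 1, 0, 0))
  expect_equal(average_entropy(dist), 0.5)  # half uniform, half degenerate
})

test_that("code distributions count every subject on every pair", {
  coh <- small_cohort(seed = 43)
  sp <- split_trials(coh, seed = 43)
  enr <- enroll_cohort(dplyr::filter(sp, split == "train"),
                       dplyr::filter(sp, split == "validation"))
  dist <- code_distribution(enr)
  expect_equal(nrow(dist), nrow(enr$model$pairs))
  counts <- as.matrix(dist[c("n00", "n01", "n10", "n11")])
  expect_true(all(rowSums(counts) == length(enr$subjects)))
  ent <- average_entropy(enr)
  expect_gte(ent, 0); expect_lte(ent, 1)
})

test_that("accuracy and FAR are non-decreasing in gamma", {
  coh <- small_cohort(seed = 44)
  sp <- split_trials(coh, seed = 44)
  enr <- enroll_cohort(dplyr::filter(sp, split == "train"),
                       dplyr::filter(sp, split == "validation"))
  sw <- sweep_gamma(enr, dplyr::filter(sp, split == "test"),
                    gammas = seq(0, 1, by = 0.05))
  expect_true(all(diff(sw$mean_accuracy) >= 0))
  expect_true(all(diff(sw$pooled_far) >= 0))
  expect_equal(sw$mean_accuracy[length(sw$gamma)], 1)
  expect_equal(sw$pooled_far[length(sw$gamma)], 1)
})

test_that("cross-context acceptance is total for cloned features and zero for reflected ones", {
  coh <- small_cohort(seed = 45)
  sp <- split_trials(coh, seed = 45)
  tr <- dplyr::filter(sp, split == "train")
  enr <- enroll_cohort(tr, dplyr::filter(sp, split == "validation"))

  clone <- dplyr::mutate(tr, context_id = "c02")
  expect_equal(as.numeric(cross_context_far(enr, clone)), 1.0)

  cols <- feature_cols(tr)
  reflected <- tr
  reflected[cols] <- as.data.frame(
    sweep(-sweep(as.matrix(tr[cols]), 2, enr$model$mu_pop), 2, -enr$model$mu_pop))
  expect_equal(as.numeric(cross_context_far(enr, reflected)), 0.0)
})
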
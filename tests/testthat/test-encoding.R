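test_that("build_sentence concatenates name and description with one space", {
  expect_identical(
    build_sentence("MMSE", "Mini mental state exam total"),
    "MMSE Mini mental state exam total"
  )
  expect_identical(build_sentence("CDRSB", ""), "CDRSB")
  # whitespace-only descriptions are treated as absent
  expect_identical(build_sentence("age_at_visit", " "), "age_at_visit")
  expect_error(build_sentence("", "x"), class = "cohortmapr_argument_error")
  expect_identical(
    build_sentence(c("a", "b"), c("d1", "")), c("a d1", "b")
  )
})

test_that("the hashed n-gram encoder is deterministic, case-folded and unit-norm", {
  enc <- ngram_encoder(dimension = 128L, seed = 3L)
  v1 <- drop(encode_text(enc, "age"))
  v2 <- drop(encode_text(enc, "age"))
  expect_identical(v1, v2)
  expect_identical(drop(encode_text(enc, "AGE")), v1)
  expect_equal(sum(v1^2), 1, tolerance = 1e-12)
  expect_equal(length(v1), 128L)
  expect_error(encode_text(enc, ""), class = "cohortmapr_argument_error")

  # baseline_encode is the one-shot wrapper over the same encoder
  expect_identical(baseline_encode("age", 128L, 3L), v1)

  # shared-gram geometry: the lateralized near-duplicate is far closer than an
  # unrelated name
  a <- baseline_encode("Lhippo_FS_adj", 256L, 1L)
  b <- baseline_encode("Rhippo_FS_adj", 256L, 1L)
  c <- baseline_encode("Age", 256L, 1L)
  expect_lt(sqrt(sum((a - b)^2)), sqrt(sum((a - c)^2)))
})

test_that("the pair classifier separates a linearly separable toy set", {
  set.seed(42)
  dup <- replicate(20, paste(sample(letters[1:10], 8, TRUE), collapse = ""))
  disj_a <- replicate(20, paste(sample(letters[1:6], 8, TRUE), collapse = ""))
  disj_b <- replicate(20, paste(sample(LETTERS[20:26], 8, TRUE), collapse = ""))
  pairs <- rbind(
    data.frame(sentence_a = dup, sentence_b = dup, label = 1L, weight = 0.9),
    data.frame(sentence_a = disj_a, sentence_b = tolower(disj_b), label = 0L, weight = 0.1)
  )
  enc <- ngram_encoder(128L, 1L)
  clf <- train_pair_classifier(pairs, enc, epochs = 100L)
  p <- vapply(seq_len(nrow(pairs)), function(i) {
    pair_score(clf, pairs$sentence_a[i], pairs$sentence_b[i])
  }, numeric(1))
  expect_true(all(p >= 0 & p <= 1))
  acc <- mean((p > 0.5) == (pairs$label == 1L))
  expect_gte(acc, 0.95)

  # training loss never rises above its initialization value
  expect_true(all(diff(clf$history) <= 1e-12))
  expect_lte(tail(clf$history, 1), clf$history[1])

  # determinism: refitting gives identical weights
  clf2 <- train_pair_classifier(pairs, enc, epochs = 100L)
  expect_identical(clf$weights, clf2$weights)

  expect_error(
    train_pair_classifier(pairs[pairs$label == 1L, ], enc),
    class = "cohortmapr_training_error"
  )
  expect_error(
    train_pair_classifier(pairs[0L, ], enc),
    class = "cohortmapr_training_error"
  )
})

test_that("doubling the positive weight increases the initial weighted loss of positives", {
  cdm <- age_cdm()
  pos <- generate_positive_pairs(cdm)
  neg <- new_pairs_for_test(pos)
  enc <- ngram_encoder(64L, 1L)
  base <- train_pair_classifier(
    assign_class_weights(rbind(pos, neg), 0.1, 0.9), enc, epochs = 0L
  )
  doubled <- train_pair_classifier(
    assign_class_weights(rbind(pos, neg), 0.1, 1.8), enc, epochs = 0L
  )
  # at zero-initialization every pair scores 0.5, so the gap is exactly the
  # extra positive contribution
  expect_gt(doubled$history[1], base$history[1])
  expect_equal(
    doubled$history[1] - base$history[1],
    0.9 * log(2) * nrow(pos) / (2 * nrow(pos)),
    tolerance = 1e-12
  )
})

test_that("the embedder tightens alias-to-term geometry and honors its contracts", {
  spec <- synthetic_spec(n_terms = 50L, n_cohorts = 4L,
                         lateralized_fraction = 0.2, seed = 77L)
  terms <- generate_reference_terms(spec)
  cdm <- generate_cohort_variants(terms, spec)
  base <- ngram_encoder(256L, 77L)

  # zero epochs: encoder output identical to init
  zero <- train_embedder(cdm, base, epochs = 0L, seed = 1L)
  texts <- c("hippocampus volume", "EDUC", "csf ab42")
  expect_equal(encode_text(zero, texts), encode_text(base, texts))

  fitted <- train_embedder(cdm, base, epochs = 40L, seed = 1L)
  # determinism under the seed
  fitted2 <- train_embedder(cdm, base, epochs = 40L, seed = 1L)
  expect_identical(fitted$scale, fitted2$scale)

  # held-out aliases sit closer to their own term than to same-modality others
  unseen <- generate_unseen_cohort(terms, spec, cdm)
  expect_gt(embedding_margin(fitted, cdm, unseen, seed = 9L), 0)

  # needs variables under >= 2 terms
  lonely <- new_cdm(
    terms = data.frame(term_id = "T1", name = "Age"),
    variables = data.frame(name = "age", source_id = "A", term_id = "T1")
  )
  expect_error(train_embedder(lonely, base), class = "cohortmapr_training_error")
})

test_that("reference-term embedding tables are complete, unique and reproducible", {
  cdm <- toy_cdm()
  enc <- ngram_encoder(64L, 2L)
  tv <- embed_reference_terms(cdm, enc)
  expect_equal(nrow(tv), nrow(cdm$terms))
  expect_false(anyDuplicated(rownames(tv)) > 0)
  expect_identical(tv, embed_reference_terms(cdm, enc))
})

test_that("manual encoder and classifier honor the plug-in contracts", {
  enc <- manual_encoder(function(x) c(nchar(x), 1), dimension = 2L)
  m <- encode_text(enc, c("ab", "abcd"))
  expect_equal(m[, 1], c(2, 4))
  clf <- manual_pair_classifier(function(a, b) if (a == b) 1 else 0)
  expect_equal(pair_scores(clf, "x", c("x", "y")), c(1, 0))
  bad <- manual_pair_classifier(function(a, b) 2)
  expect_error(pair_scores(bad, "x", "y"), class = "cohortmapr_state_error")
})
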
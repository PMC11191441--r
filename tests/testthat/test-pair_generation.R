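test_that("positive pairs follow the mapping edges in both modes", {
  cdm <- age_cdm()
  expect_equal(nrow(generate_positive_pairs(cdm, "ref_to_variable")), 4L)
  # every unordered pair from {term} U aliases: C(5, 2)
  all_comb <- generate_positive_pairs(cdm, "all_combinations")
  expect_equal(nrow(all_comb), choose(5, 2))
  expect_true(all(all_comb$label == 1L))
  # canonical within-pair order and deterministic output order
  expect_identical(all_comb, generate_positive_pairs(cdm, "all_combinations"))

  lonely <- new_cdm(terms = data.frame(term_id = "T1", name = "Age"))
  expect_equal(nrow(generate_positive_pairs(lonely)), 0L)
  expect_equal(nrow(generate_positive_pairs(lonely, "ref_to_variable")), 0L)
})

test_that("negative pairs stay within modality, across terms, disjoint from positives", {
  cdm <- toy_cdm()
  neg <- generate_negative_pairs(cdm, 8L, seed = 7L)
  expect_equal(nrow(neg), 8L)
  expect_true(all(neg$label == 0L))

  # exhaustive lookup: no negative joins items of one term or two modalities
  items <- rbind(
    data.frame(
      sentence = build_sentence(cdm$terms$name, cdm$terms$description),
      term_id = cdm$terms$term_id, modality = cdm$terms$modality
    ),
    data.frame(
      sentence = build_sentence(cdm$variables$name, cdm$variables$description),
      term_id = cdm$variables$term_id, modality = cdm$variables$modality
    )
  )
  for (i in seq_len(nrow(neg))) {
    ta <- items$term_id[items$sentence == neg$sentence_a[i]]
    tb <- items$term_id[items$sentence == neg$sentence_b[i]]
    expect_length(intersect(ta, tb), 0L)
    ma <- items$modality[items$sentence == neg$sentence_a[i]]
    mb <- items$modality[items$sentence == neg$sentence_b[i]]
    expect_true(length(intersect(ma, mb)) > 0L)
  }
  pos <- generate_positive_pairs(cdm, "all_combinations")
  expect_length(
    intersect(
      paste(neg$sentence_a, neg$sentence_b),
      paste(pos$sentence_a, pos$sentence_b)
    ),
    0L
  )
  # lateralized near-duplicates are eligible hard negatives
  full <- generate_negative_pairs(cdm, 12L, seed = 1L)
  lat <- grepl("hippo", full$sentence_a) & grepl("hippo", full$sentence_b)
  expect_true(any(lat))

  # reproducible under the seed
  expect_identical(neg, generate_negative_pairs(cdm, 8L, seed = 7L))
  expect_false(identical(neg, generate_negative_pairs(cdm, 8L, seed = 8L)))
})

test_that("infeasible negative draws raise a capacity error naming the maximum", {
  # every modality holds a single term: no valid pair exists
  cdm <- new_cdm(
    terms = data.frame(
      term_id = c("T1", "T2"), name = c("Age", "Hippocampus Volume"),
      modality = c("Demographics", "MRI")
    ),
    variables = data.frame(
      name = c("age", "hippo"), source_id = "A", term_id = c("T1", "T2")
    )
  )
  expect_error(
    generate_negative_pairs(cdm, 1L, seed = 1L),
    "maximum available is 0", class = "cohortmapr_capacity_error"
  )
  # and a feasible CDM errors only beyond its true capacity
  cdm2 <- toy_cdm()
  err <- tryCatch(
    generate_negative_pairs(cdm2, 10000L, seed = 1L),
    cohortmapr_capacity_error = function(e) conditionMessage(e)
  )
  cap <- as.integer(sub(".*maximum available is (\\d+).*", "\\1", err))
  expect_equal(nrow(generate_negative_pairs(cdm2, cap, seed = 1L)), cap)
})

test_that("class weights default to 0.1/0.9 and reject non-positive values", {
  cdm <- age_cdm()
  pos <- generate_positive_pairs(cdm)
  mixed <- rbind(pos, new_pairs_for_test(pos))
  w <- assign_class_weights(mixed)
  expect_true(all(w$weight[w$label == 1L] == 0.9))
  expect_true(all(w$weight[w$label == 0L] == 0.1))
  unw <- assign_class_weights(mixed, 1, 1)
  expect_true(all(unw$weight == 1))
  expect_error(assign_class_weights(mixed, 0, 1), class = "cohortmapr_argument_error")
  empty <- pos[0L, ]
  expect_equal(nrow(assign_class_weights(empty)), 0L)
})

test_that("split_dataset partitions with floor sizes, remainder to train", {
  pairs <- data.frame(
    sentence_a = sprintf("a%03d", 1:100), sentence_b = sprintf("b%03d", 1:100),
    label = rep(c(0L, 1L), 50), weight = 1
  )
  sp <- split_dataset(pairs, c(0.80, 0.04, 0.16), seed = 5L)
  expect_equal(nrow(sp$train), 80L)
  expect_equal(nrow(sp$test), 4L)
  expect_equal(nrow(sp$validation), 16L)

  # partition: union = all, pairwise disjoint
  got <- sort(c(sp$train$sentence_a, sp$test$sentence_a, sp$validation$sentence_a))
  expect_identical(got, sort(pairs$sentence_a))

  # n = 25: floors 20/1/4, remainder 0
  sp25 <- split_dataset(pairs[1:25, ], c(0.80, 0.04, 0.16), seed = 5L)
  expect_equal(
    c(nrow(sp25$train), nrow(sp25$test), nrow(sp25$validation)), c(20L, 1L, 4L)
  )

  # same seed bit-identical, different seed (almost surely) different
  sp2 <- split_dataset(pairs, c(0.80, 0.04, 0.16), seed = 5L)
  expect_identical(sp, sp2)
  sp3 <- split_dataset(pairs, c(0.80, 0.04, 0.16), seed = 6L)
  expect_false(identical(sp$train$sentence_a, sp3$train$sentence_a))

  # n = 0: three empty parts
  sp0 <- split_dataset(pairs[0L, ], seed = 1L)
  expect_equal(nrow(sp0$train) + nrow(sp0$test) + nrow(sp0$validation), 0L)

  expect_error(
    split_dataset(pairs, c(0.8, 0.1, 0.2), seed = 1L),
    class = "cohortmapr_argument_error"
  )
})

test_that("pairs export to the documented CSV layout", {
  cdm <- age_cdm()
  pos <- assign_class_weights(generate_positive_pairs(cdm))
  p <- file.path(tempdir(), "pairs.csv")
  write_pairs_csv(pos, p)
  back <- read.csv(p, colClasses = c("character", "character", "integer", "numeric"))
  expect_identical(names(back), c("sentence_a", "sentence_b", "label", "weight"))
  expect_equal(nrow(back), nrow(pos))
})
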
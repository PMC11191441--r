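test_that("get_candidates equals an exhaustive sorted scan", {
  m <- rbind(c(0, 0), c(1, 0), c(0, 2))
  rownames(m) <- c("TA", "TB", "TC")
  r <- get_candidates(c(0.9, 0), m, 2L)
  expect_identical(r$entries$term_id, c("TB", "TA"))
  expect_equal(r$entries$distance, c(0.1, 0.9), tolerance = 1e-12)

  # K >= |table| returns everything fully sorted
  r3 <- get_candidates(c(0.9, 0), m, 10L)
  expect_identical(r3$entries$term_id, c("TB", "TA", "TC"))

  # identical vectors: lexicographically smaller term_id first
  m2 <- rbind(c(1, 1), c(1, 1))
  rownames(m2) <- c("T2", "T1")
  expect_identical(get_candidates(c(0, 0), m2, 2L)$entries$term_id, c("T1", "T2"))

  # random equivalence with the brute-force oracle
  set.seed(31)
  mm <- matrix(rnorm(120 * 8), 120, 8)
  rownames(mm) <- sprintf("T%03d", sample(120))
  for (i in 1:25) {
    q <- rnorm(8)
    for (k in c(1L, 4L, 120L)) {
      expect_identical(
        get_candidates(q, mm, k)$entries$term_id,
        brute_candidates(q, mm, k)
      )
    }
  }

  expect_error(
    get_candidates(c(0, 0), m[0, , drop = FALSE], 1L),
    class = "cohortmapr_state_error"
  )
  expect_error(get_candidates(c(0, 0), m, 0), class = "cohortmapr_argument_error")
})

test_that("prior-knowledge expansion adds exactly the candidates' aliases", {
  spec <- synthetic_spec(n_terms = 5L, n_cohorts = 2L,
                         lateralized_fraction = 0, seed = 9L)
  terms <- generate_reference_terms(spec)
  cdm <- generate_cohort_variants(terms, spec)
  enc <- ngram_encoder(64L, 1L)
  tv <- embed_reference_terms(cdm, enc)
  ranking <- get_candidates(drop(encode_text(enc, "query text")), tv, 5L)
  expanded <- expand_with_prior_knowledge(ranking, cdm)
  # 5 candidates x 2 aliases each: 15 comparison items in total
  expect_identical(expanded$entries, ranking$entries)
  expect_equal(nrow(expanded$enrichments), 10L)
  expect_true(all(expanded$enrichments$term_id %in% expanded$entries$term_id))

  # zero aliases: enrichment empty, ranking otherwise unchanged
  bare <- new_cdm(terms = cdm$terms)
  tv2 <- embed_reference_terms(bare, enc)
  r2 <- get_candidates(drop(encode_text(enc, "query text")), tv2, 5L)
  e2 <- expand_with_prior_knowledge(r2, bare)
  expect_equal(nrow(e2$enrichments), 0L)
  expect_identical(e2$entries, r2$entries)
})

test_that("select_winner thresholds on probability, then blends, then reverses aliases", {
  cdm <- toy_cdm()
  enc <- ngram_encoder(64L, 1L)
  tv <- embed_reference_terms(cdm, enc)
  q <- drop(encode_text(enc, "some query"))
  ranking <- get_candidates(q, tv, 4L)
  sent <- setNames(ranking$entries$sentence, ranking$entries$term_id)

  probs <- list(0.8, 0.6, 0.3, 0.2)
  names(probs) <- sent[c("CDRSB", "MMSE", "LHIP", "RHIP")]
  clf <- lookup_classifier(probs)
  cfg <- harmonization_config(K = 4L, w1 = 1, w2 = 0, threshold = 0.5)
  res <- select_winner("some query", "", ranking, clf, cfg)
  expect_identical(res$winner, "CDRSB")
  expect_equal(res$probability, 0.8)
  expect_identical(res$status, "matched")

  # all below threshold: no_match with empty winner
  high <- harmonization_config(K = 4L, w1 = 1, w2 = 0, threshold = 0.9)
  res2 <- select_winner("some query", "", ranking, clf, high)
  expect_identical(res2$status, "no_match")
  expect_true(is.na(res2$winner))

  # a winning enrichment resolves to its parent term
  expanded <- expand_with_prior_knowledge(ranking, cdm)
  probs3 <- as.list(rep(0.55, nrow(expanded$entries) + nrow(expanded$enrichments)))
  names(probs3) <- c(expanded$entries$sentence, expanded$enrichments$sentence)
  probs3[["cdr_sb"]] <- 0.99
  res3 <- select_winner("cdr_sb", "", expanded, lookup_classifier(probs3), cfg)
  expect_identical(res3$winner, "CDRSB")
  expect_equal(res3$probability, 0.99)
})

test_that("harmonize_variable composes the cascade deterministically", {
  bench <- small_benchmark()
  cdm <- bench$cdm
  pl <- bench$pipeline

  # identity: a term fed back as its own name+description maps to itself
  tm <- cdm$terms[7L, ]
  res <- harmonize_variable(
    tm$name, tm$description, cdm, pl$encoder, pl$classifier,
    harmonization_config(K = 5L, threshold = 0, seed = 101L),
    term_vectors = pl$term_vectors
  )
  expect_identical(res$winner, tm$term_id)
  expect_equal(res$candidates$entries$distance[1L], 0, tolerance = 1e-12)

  # degenerate string-only configuration equals the baseline, tie-breaks included
  cfg <- harmonization_config(
    K = nrow(cdm$terms), w1 = 0, w2 = 1, threshold = 0, seed = 101L
  )
  for (i in seq(1L, nrow(cdm$variables), by = 7L)) {
    v <- cdm$variables[i, ]
    a <- harmonize_variable(v$name, v$description, cdm, pl$encoder,
                            pl$classifier, cfg, term_vectors = pl$term_vectors)
    b <- string_match_baseline(v$name, cdm)
    expect_identical(a$winner, b$winner)
  }

  # gibberish under a stringent threshold: no_match
  res_g <- harmonize_variable(
    "qqqxxzzwy", "", cdm, pl$encoder, pl$classifier,
    harmonization_config(K = 5L, threshold = 0.99, seed = 101L),
    term_vectors = pl$term_vectors
  )
  expect_identical(res_g$status, "no_match")

  expect_error(
    harmonize_variable("", "", cdm, pl$encoder, pl$classifier),
    class = "cohortmapr_argument_error"
  )
})

test_that("dictionary harmonization preserves order, isolates rows, flags empties", {
  bench <- small_benchmark()
  rows <- data.frame(
    name = c(bench$unseen$name[1L], "", bench$unseen$name[1L]),
    description = c(bench$unseen$description[1L], "", bench$unseen$description[1L])
  )
  res <- harmonize_dictionary(rows, bench$cdm, bench$pipeline$encoder,
                              bench$pipeline$classifier,
                              harmonization_config(seed = 101L))
  expect_length(res, 3L)
  expect_identical(res[[2L]]$status, "error")
  # duplicated rows give identical results; valid rows unaffected by the bad one
  expect_identical(res[[1L]]$winner, res[[3L]]$winner)
  expect_identical(res[[1L]]$probability, res[[3L]]$probability)
  df <- as.data.frame(res)
  expect_identical(
    names(df),
    c("input_variable", "input_description", "term_id", "probability",
      "combined_score", "status", "candidates")
  )
})

test_that("hit@K is nondecreasing in K and prior knowledge is a no-op without aliases", {
  bench <- small_benchmark()
  cdm <- bench$cdm
  pl <- bench$pipeline
  full_cfg <- harmonization_config(
    K = nrow(cdm$terms), threshold = 0, seed = 101L
  )
  res <- harmonize_dictionary(bench$unseen, cdm, pl$encoder, pl$classifier, full_cfg)
  rankings <- lapply(res, function(r) r$candidates)
  rates <- vapply(c(1L, 2L, 5L, 10L, 20L, 40L), function(k) {
    hitk_rate(rankings, bench$unseen$term_id, k)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_equal(rates[length(rates)], 100)

  # alias-free CDM: enabling prior knowledge cannot change any result
  bare <- new_cdm(terms = cdm$terms)
  enc <- pl$encoder
  clf <- pl$classifier
  for (i in c(1L, 11L, 21L)) {
    u <- bench$unseen[i, ]
    off <- harmonize_variable(u$name, u$description, bare, enc, clf,
                              harmonization_config(K = 5L, threshold = 0, seed = 1L))
    on <- harmonize_variable(u$name, u$description, bare, enc, clf,
                             harmonization_config(K = 5L, threshold = 0,
                                                  use_prior_knowledge = TRUE, seed = 1L))
    expect_identical(off$winner, on$winner)
    expect_identical(off$probability, on$probability)
  }
})
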
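# Independent oracles and fixture builders shared across test files.

# Quadratic dynamic-programming Levenshtein oracle, written independently of
# the package implementation.
lev_oracle <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca)
  m <- length(cb)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1L] <- 0:n
  d[1L, ] <- 0:m
  if (n && m) {
    for (i in seq_len(n)) {
      for (j in seq_len(m)) {
        cost <- if (ca[i] == cb[j]) 0L else 1L
        d[i + 1L, j + 1L] <- min(
          d[i, j + 1L] + 1L, d[i + 1L, j] + 1L, d[i, j] + cost
        )
      }
    }
  }
  d[n + 1L, m + 1L]
}

# Brute-force K-nearest oracle: per-row Euclidean distances, full sort, ties
# by term id.
brute_candidates <- function(query, m, k) {
  d <- apply(m, 1L, function(row) sqrt(sum((row - query)^2)))
  ids <- rownames(m)
  o <- order(d, ids, method = "radix")
  ids[o][seq_len(min(k, nrow(m)))]
}

# The "Age" toy CDM: one term, four cohort spellings.
age_cdm <- function() {
  new_cdm(
    terms = data.frame(
      term_id = "AGE", name = "Age", description = "Age of the participant",
      ontology_id = "NCIT:C25150", modality = "Demographics",
      stringsAsFactors = FALSE
    ),
    variables = data.frame(
      name = c("age", "PTAGE", "samplingAge", "age_at_visit"),
      source_id = c("cohortA", "cohortA", "cohortB", "cohortC"),
      term_id = "AGE", stringsAsFactors = FALSE
    )
  )
}

# Two-modality toy CDM with lateralized MRI hard negatives and aliases.
toy_cdm <- function() {
  new_cdm(
    terms = data.frame(
      term_id = c("CDRSB", "LHIP", "RHIP", "MMSE"),
      name = c(
        "Clinical Dementia Rating Sum of Boxes",
        "Hippocampus Volume (L)", "Hippocampus Volume (R)",
        "Mini Mental State Examination"
      ),
      description = c(
        "Sum of boxes score", "Left hippocampus volume",
        "Right hippocampus volume", "Total MMSE score"
      ),
      ontology_id = "", modality = c("Clinical", "MRI", "MRI", "Clinical"),
      stringsAsFactors = FALSE
    ),
    variables = data.frame(
      name = c("CDRSB", "CDR_SOB", "cdr_sb", "Lhippo_FS_adj", "Rhippo_FS_adj", "mmse"),
      source_id = c("ADNI", "EPAD", "NACC", "ADNI", "ADNI", "ADNI"),
      term_id = c("CDRSB", "CDRSB", "CDRSB", "LHIP", "RHIP", "MMSE"),
      description = c("", "", "", "Left hippocampus", "Right hippocampus", ""),
      stringsAsFactors = FALSE
    )
  )
}

# Small trained fixtures reused by retrieval/evaluation/cli tests; built once
# per test run.
fixture_env <- new.env()

small_benchmark <- function() {
  if (is.null(fixture_env$bench)) {
    spec <- synthetic_spec(
      n_terms = 40L, n_cohorts = 3L, lateralized_fraction = 0.3, seed = 101L
    )
    terms <- generate_reference_terms(spec)
    cdm <- generate_cohort_variants(terms, spec)
    pipeline <- train_pipeline(cdm, harmonization_config(seed = 101L))
    unseen <- generate_unseen_cohort(terms, spec, cdm)
    fixture_env$bench <- list(
      spec = spec, terms = terms, cdm = cdm, pipeline = pipeline, unseen = unseen
    )
  }
  fixture_env$bench
}

# Label-0 companions for weighting tests.
new_pairs_for_test <- function(pos) {
  data.frame(
    sentence_a = paste0(pos$sentence_a, " x"),
    sentence_b = paste0(pos$sentence_b, " y"),
    label = 0L, weight = 1, stringsAsFactors = FALSE
  )
}

# Deterministic stub classifier: probabilities looked up by candidate
# sentence.
lookup_classifier <- function(probs) {
  manual_pair_classifier(function(a, b) {
    if (!is.null(probs[[b]])) probs[[b]] else 0.5
  })
}
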
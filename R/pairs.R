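term_sentences <- function(cdm) {
  stats::setNames(
    build_sentence(cdm$terms$name, cdm$terms$description),
    cdm$terms$term_id
  )
}

# One row per term sentence and per mapped variable sentence, with the owning
# term and modality; the item universe both pair generators draw from.
cdm_items <- function(cdm) {
  terms <- cdm$terms
  vars <- cdm$variables
  items <- data.frame(
    sentence = build_sentence(terms$name, terms$description),
    term_id = terms$term_id,
    modality = terms$modality,
    stringsAsFactors = FALSE
  )
  if (nrow(vars)) {
    items <- rbind(items, data.frame(
      sentence = build_sentence(vars$name, vars$description),
      term_id = vars$term_id,
      modality = vars$modality,
      stringsAsFactors = FALSE
    ))
  }
  items
}

new_pairs <- function(sentence_a, sentence_b, label, weight = 1) {
  data.frame(
    sentence_a = sentence_a, sentence_b = sentence_b,
    label = as.integer(label), weight = weight,
    stringsAsFactors = FALSE
  )
}

empty_pairs <- function() {
  new_pairs(character(), character(), integer(), numeric())
}

#' Generate positive (semantically equivalent) training pairs
#'
#' Positives are drawn from the curated mapping edges of the CDM. In
#' `all_combinations` mode (default) every unordered pair from
#' `{reference term} U {its aliases}` is emitted per term, i.e.
#' `choose(1 + n_aliases, 2)` pairs; in `ref_to_variable` mode exactly one
#' `(term, variable)` pair per mapping edge. All pairs carry label 1 and are
#' returned with canonically ordered sentences in deterministic order.
#'
#' @param cdm a [new_cdm()] object.
#' @param mode `"all_combinations"` or `"ref_to_variable"`.
#' @return data.frame with columns `sentence_a`, `sentence_b`, `label`,
#'   `weight` (weight 1 until [assign_class_weights()] is applied).
#' @export
generate_positive_pairs <- function(cdm, mode = c("all_combinations", "ref_to_variable")) {
  mode <- match.arg(mode)
  validate_cdm(cdm)
  ts <- term_sentences(cdm)
  vars <- cdm$variables
  if (nrow(vars) == 0L) return(empty_pairs())
  vs <- build_sentence(vars$name, vars$description)

  if (mode == "ref_to_variable") {
    a <- ts[vars$term_id]
    cp <- canonical_pairs(unname(a), vs)
    out <- new_pairs(cp$first, cp$second, 1L)
  } else {
    chunks <- lapply(sort_chr(unique(vars$term_id)), function(tid) {
      sents <- c(ts[[tid]], vs[vars$term_id == tid])
      if (length(sents) < 2L) return(NULL)
      idx <- utils::combn(length(sents), 2L)
      canonical_pairs(sents[idx[1L, ]], sents[idx[2L, ]])
    })
    cp <- do.call(rbind, chunks)
    if (is.null(cp)) return(empty_pairs())
    out <- new_pairs(cp$first, cp$second, 1L)
  }
  sort_df(out, c("sentence_a", "sentence_b"))
}

# Per-modality pool of distinct eligible negative pairs: items of the same
# modality belonging to different reference terms, minus anything that is
# already a positive pair.
negative_pair_pool <- function(cdm) {
  items <- cdm_items(cdm)
  pos <- generate_positive_pairs(cdm, "all_combinations")
  pos_keys <- pair_key(pos$sentence_a, pos$sentence_b)
  pools <- list()
  for (m in sort_chr(unique(items$modality))) {
    sub <- items[items$modality == m, , drop = FALSE]
    if (nrow(sub) < 2L || length(unique(sub$term_id)) < 2L) next
    idx <- utils::combn(nrow(sub), 2L)
    keep <- sub$term_id[idx[1L, ]] != sub$term_id[idx[2L, ]]
    if (!any(keep)) next
    cp <- canonical_pairs(sub$sentence[idx[1L, keep]], sub$sentence[idx[2L, keep]])
    keys <- key2(cp$first, cp$second)
    ok <- !duplicated(keys) & !keys %in% pos_keys
    if (!any(ok)) next
    pools[[m]] <- sort_df(cp[ok, , drop = FALSE], c("first", "second"))
  }
  pools
}

#' Generate hard-negative training pairs within modalities
#'
#' Negatives join two items (reference-term or variable sentences) that share
#' a modality but belong to different reference terms — the confusable cases,
#' such as left/right lateralized volumes with near-identical names. Exactly
#' `n_required` distinct pairs are drawn without replacement, never
#' duplicating a positive pair, stratified across modalities proportionally to
#' each modality's positive-pair count. Sampling is reproducible under `seed`.
#'
#' @param cdm a [new_cdm()] object.
#' @param n_required number of negative pairs (e.g. the positive count, for a
#'   balanced design).
#' @param seed integer seed.
#' @return data.frame as in [generate_positive_pairs()], all labels 0.
#' @export
generate_negative_pairs <- function(cdm, n_required, seed = 1L) {
  validate_cdm(cdm)
  if (!is.numeric(n_required) || length(n_required) != 1L || n_required < 0) {
    abort_argument("n_required must be a non-negative count")
  }
  n_required <- as.integer(n_required)
  if (n_required == 0L) return(empty_pairs())

  pools <- negative_pair_pool(cdm)
  caps <- vapply(pools, nrow, integer(1))
  total <- sum(caps)
  if (total < n_required) {
    abort_capacity(sprintf(
      "cannot draw %d distinct negative pairs; maximum available is %d",
      n_required, total
    ))
  }

  # proportional allocation by per-modality positive-pair count, capacity-capped
  n_alias <- table(factor(cdm$variables$term_id, levels = cdm$terms$term_id))
  pos_per_term <- choose(1L + as.numeric(n_alias), 2L)
  pos_by_mod <- tapply(pos_per_term, factor(cdm$terms$modality, levels = names(pools)), sum)
  weights <- as.numeric(pos_by_mod)
  weights[is.na(weights)] <- 0
  if (sum(weights) == 0) weights <- as.numeric(caps)
  alloc <- floor(n_required * weights / sum(weights))
  rem <- n_required - sum(alloc)
  if (rem > 0L) {
    frac <- n_required * weights / sum(weights) - alloc
    o <- radix_order(-frac, names(pools))
    bump <- o[seq_len(rem)]
    alloc[bump] <- alloc[bump] + 1L
  }
  alloc <- pmin(alloc, caps)
  deficit <- n_required - sum(alloc)
  while (deficit > 0L) {
    spare <- caps - alloc
    for (i in radix_order(names(pools))) {
      take <- min(spare[i], deficit)
      alloc[i] <- alloc[i] + take
      deficit <- deficit - take
      if (deficit == 0L) break
    }
  }

  out <- with_seed(seed, {
    chunks <- lapply(seq_along(pools), function(i) {
      if (alloc[i] == 0L) return(NULL)
      pool <- pools[[i]]
      pool[sample.int(nrow(pool), alloc[i]), , drop = FALSE]
    })
    do.call(rbind, chunks)
  })
  sort_df(new_pairs(out$first, out$second, 0L), c("sentence_a", "sentence_b"))
}

#' Assign class weights to labeled pairs
#'
#' The training loss weights negatives and positives differently (defaults
#' 0.1 and 0.9) to mirror the intended application regime in which almost all
#' candidate pairings are non-equivalent.
#'
#' @param pairs data.frame from the pair generators.
#' @param w_neg weight for label-0 pairs (> 0, default 0.1).
#' @param w_pos weight for label-1 pairs (> 0, default 0.9).
#' @return `pairs` with its `weight` column set.
#' @export
assign_class_weights <- function(pairs, w_neg = 0.1, w_pos = 0.9) {
  if (!is.numeric(w_neg) || length(w_neg) != 1L || !is.finite(w_neg) || w_neg <= 0 ||
      !is.numeric(w_pos) || length(w_pos) != 1L || !is.finite(w_pos) || w_pos <= 0) {
    abort_argument("class weights must be positive")
  }
  if (nrow(pairs) == 0L) return(pairs)
  pairs$weight <- ifelse(pairs$label == 1L, w_pos, w_neg)
  pairs
}

#' Split labeled pairs into train / test / validation parts
#'
#' Sizes are `floor(fraction * n)` per part with the remainder assigned to the
#' training part; the shuffle is reproducible under `seed`. The default
#' fractions are 80/4/16 (train/test/validation, the test part deliberately
#' smaller than validation).
#'
#' @param pairs data.frame of labeled pairs.
#' @param fractions numeric length-3 vector `(train, test, validation)`
#'   summing to 1.
#' @param seed integer seed.
#' @return A list of class `dataset_split` with elements `train`, `test`,
#'   `validation` (disjoint data.frames partitioning `pairs`) and `fractions`.
#' @export
split_dataset <- function(pairs, fractions = c(0.80, 0.04, 0.16), seed = 1L) {
  if (length(fractions) != 3L || any(!is.finite(fractions)) || any(fractions < 0)) {
    abort_argument("fractions must be three non-negative numbers")
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    abort_argument("fractions must sum to 1")
  }
  n <- nrow(pairs)
  n_test <- floor(fractions[2L] * n)
  n_val <- floor(fractions[3L] * n)
  n_train <- n - n_test - n_val
  idx <- with_seed(seed, sample.int(n))
  take <- function(i) {
    out <- pairs[i, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  structure(
    list(
      train = take(idx[seq_len(n_train)]),
      test = take(idx[n_train + seq_len(n_test)]),
      validation = take(idx[n_train + n_test + seq_len(n_val)]),
      fractions = fractions
    ),
    class = "dataset_split"
  )
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf(
    "<dataset_split> train=%d test=%d validation=%d (fractions %s)\n",
    nrow(x$train), nrow(x$test), nrow(x$validation),
    paste(x$fractions, collapse = "/")
  ))
  invisible(x)
}

#' Write labeled pairs to CSV
#'
#' @param pairs data.frame of labeled pairs.
#' @param path output path; columns `sentence_a,sentence_b,label,weight`.
#' @return `path`, invisibly.
#' @export
write_pairs_csv <- function(pairs, path) {
  utils::write.csv(
    pairs[c("sentence_a", "sentence_b", "label", "weight")],
    path, row.names = FALSE, fileEncoding = "UTF-8"
  )
  invisible(path)
}
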
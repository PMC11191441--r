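match_result <- function(input_name, input_description, winner, probability,
                         combined_score, status, candidates = NULL) {
  structure(
    list(
      input_name = input_name, input_description = input_description,
      winner = winner, probability = probability,
      combined_score = combined_score, status = status,
      candidates = candidates
    ),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  if (x$status == "matched") {
    cat(sprintf(
      "<match_result> '%s' -> %s (p=%s, score=%s)\n",
      x$input_name, x$winner,
      format(x$probability, digits = 4), format(x$combined_score, digits = 4)
    ))
  } else {
    cat(sprintf("<match_result> '%s' -> %s\n", x$input_name, x$status))
  }
  invisible(x)
}

#' Retrieve the K nearest reference terms in the embedding space
#'
#' Exact scan: Euclidean distances from the query vector to every row of the
#' reference-term matrix, fully sorted ascending with ties broken by
#' lexicographically smaller term_id, truncated to `min(K, n)` entries. This
#' equals a brute-force full sort on every input (no approximate indexing;
#' exact search is cheap at common-data-model scale).
#'
#' @param query numeric query vector (the embedded query sentence).
#' @param term_vectors matrix from [embed_reference_terms()] (or any numeric
#'   matrix with term_id rownames).
#' @param K number of candidates to return.
#' @return An object of class `candidate_ranking`: list with `entries` (a
#'   data.frame `term_id`, `distance`, `name`, `sentence`, sorted by
#'   nondecreasing distance) and `enrichments` (`NULL` until
#'   [expand_with_prior_knowledge()]).
#' @export
get_candidates <- function(query, term_vectors, K) {
  if (!is.matrix(term_vectors) || nrow(term_vectors) == 0L) {
    abort_state("reference-term embedding table is empty")
  }
  if (is.null(rownames(term_vectors))) {
    abort_argument("term_vectors must carry term_id rownames")
  }
  if (!is_count(K)) abort_argument("K must be a positive integer")
  query <- as.numeric(query)
  if (length(query) != ncol(term_vectors)) {
    abort_argument("query dimension does not match the term vectors")
  }
  ids <- rownames(term_vectors)
  dist <- sqrt(colSums((t(term_vectors) - query)^2))
  o <- radix_order(dist, ids)[seq_len(min(K, nrow(term_vectors)))]
  nm <- attr(term_vectors, "term_name") %||% ids
  sent <- attr(term_vectors, "term_sentence") %||% nm
  structure(
    list(
      entries = data.frame(
        term_id = ids[o], distance = unname(dist[o]),
        name = nm[o], sentence = sent[o], stringsAsFactors = FALSE
      ),
      enrichments = NULL
    ),
    class = "candidate_ranking"
  )
}

#' @export
print.candidate_ranking <- function(x, ...) {
  cat(sprintf(
    "<candidate_ranking> %d candidates%s\n", nrow(x$entries),
    if (is.null(x$enrichments)) "" else
      sprintf(" + %d prior-mapping enrichments", nrow(x$enrichments))
  ))
  invisible(x)
}

#' Expand a candidate ranking with prior known mappings
#'
#' Adds, for every retrieved reference term, all cohort variables already
#' mapped onto it (as sentences). The entry list is unchanged; the comparison
#' set grows from K to K plus the candidates' alias count, and a winning alias
#' is later resolved back to its parent term by reversing the known mapping.
#'
#' @param ranking a [get_candidates()] result.
#' @param cdm the CDM supplying the known mappings.
#' @return `ranking` with its `enrichments` data.frame populated
#'   (`term_id`, `name`, `sentence`; zero rows if no candidate has aliases).
#' @export
expand_with_prior_knowledge <- function(ranking, cdm) {
  chunks <- lapply(ranking$entries$term_id, function(tid) {
    al <- aliases_of(cdm, tid)
    if (nrow(al) == 0L) return(NULL)
    data.frame(
      term_id = tid, name = al$name,
      sentence = build_sentence(al$name, al$description),
      stringsAsFactors = FALSE
    )
  })
  chunks <- chunks[!vapply(chunks, is.null, logical(1))]
  ranking$enrichments <- if (length(chunks)) do.call(rbind, chunks) else
    data.frame(term_id = character(), name = character(), sentence = character(),
               stringsAsFactors = FALSE)
  rownames(ranking$enrichments) <- NULL
  ranking
}

#' Threshold, blend and pick the winning reference term
#'
#' The classifier scores the query sentence against every candidate entry and
#' (if present) enrichment; items with probability below
#' `config$threshold` are eliminated; among the survivors the item maximizing
#' `w1 * probability + w2 * string_similarity` wins, with string similarity
#' computed between the query *name* and the candidate's term name (alias name
#' for enrichments). A winning enrichment is resolved to its parent term. With
#' no survivors the result is a no-match. Combined-score ties break to the
#' lexicographically smaller term_id (then direct candidates before
#' enrichments, then matched name), keeping the degenerate string-only
#' configuration exactly equivalent to [string_match_baseline()].
#'
#' @param name,description the query variable.
#' @param ranking a [get_candidates()] (optionally expanded) ranking.
#' @param classifier a pair classifier.
#' @param config a [harmonization_config()].
#' @return A `match_result` with status `"matched"` or `"no_match"`.
#' @export
select_winner <- function(name, description, ranking, classifier, config) {
  entries <- ranking$entries
  if (is.null(entries) || nrow(entries) == 0L) {
    abort_state("candidate ranking is empty")
  }
  items <- data.frame(
    term_id = entries$term_id, match_name = entries$name,
    sentence = entries$sentence, kind = "candidate",
    stringsAsFactors = FALSE
  )
  if (!is.null(ranking$enrichments) && nrow(ranking$enrichments)) {
    items <- rbind(items, data.frame(
      term_id = ranking$enrichments$term_id,
      match_name = ranking$enrichments$name,
      sentence = ranking$enrichments$sentence,
      kind = "prior_mapping", stringsAsFactors = FALSE
    ))
  }
  query_sentence <- build_sentence(name, description)
  p <- pair_scores(classifier, query_sentence, items$sentence)
  keep <- p >= config$threshold
  if (!any(keep)) {
    return(match_result(
      input_name = name, input_description = description,
      winner = NA_character_, probability = NA_real_,
      combined_score = NA_real_, status = "no_match", candidates = ranking
    ))
  }
  sims <- norm_sim_vec(name, items$match_name)
  combined <- combine_scores(p, sims, config$w1, config$w2)
  surv <- which(keep)
  best <- surv[radix_order(
    -combined[surv], items$term_id[surv], items$kind[surv], items$match_name[surv]
  )[1L]]
  match_result(
    input_name = name, input_description = description,
    winner = items$term_id[best], probability = p[best],
    combined_score = combined[best], status = "matched", candidates = ranking
  )
}

#' Harmonize a single cohort variable against a CDM
#'
#' The full inference cascade: build the query sentence, embed it, retrieve
#' the K nearest reference terms, optionally expand them with prior known
#' mappings, score all pairs with the match classifier, eliminate candidates
#' below the probability threshold, and pick the winner by the weighted blend
#' of probability and string similarity. Deterministic for fixed fitted
#' states.
#'
#' @param name variable name (non-empty).
#' @param description optional variable description (`""` for none).
#' @param cdm a [new_cdm()] object.
#' @param encoder a fitted encoder.
#' @param classifier a fitted pair classifier.
#' @param config a [harmonization_config()].
#' @param term_vectors optional precomputed [embed_reference_terms()] matrix
#'   (pass it when harmonizing many variables against one CDM).
#' @return A `match_result`.
#' @export
harmonize_variable <- function(name, description = "", cdm, encoder, classifier,
                               config = harmonization_config(),
                               term_vectors = NULL) {
  if (length(name) != 1L || is.na(name) || !nzchar(trimws(name))) {
    abort_argument("variable name must be non-empty")
  }
  description <- if (length(description) == 0L || is.na(description)) "" else description
  tv <- term_vectors %||% embed_reference_terms(cdm, encoder)
  q <- drop(encode_text(encoder, build_sentence(name, description)))
  ranking <- get_candidates(q, tv, config$K)
  if (config$use_prior_knowledge) {
    ranking <- expand_with_prior_knowledge(ranking, cdm)
  }
  select_winner(name, description, ranking, classifier, config)
}

#' Harmonize a whole data dictionary
#'
#' Applies [harmonize_variable()] row by row (rows are independent; input
#' order is preserved). Rows with an empty name are flagged with status
#' `"error"` instead of aborting the batch.
#'
#' @param rows data.frame with columns `name` (or `variable`) and optionally
#'   `description`.
#' @inheritParams harmonize_variable
#' @return A list of `match_result` objects of class `match_result_list`;
#'   convert with [as.data.frame()].
#' @export
harmonize_dictionary <- function(rows, cdm, encoder, classifier,
                                 config = harmonization_config()) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  if ("variable" %in% names(rows) && !"name" %in% names(rows)) {
    rows$name <- rows$variable
  }
  if (!"name" %in% names(rows)) abort_argument("rows require a name/variable column")
  if (!"description" %in% names(rows)) rows$description <- ""
  rows$name <- as.character(rows$name)
  rows$description <- as_chr(rows$description)
  tv <- embed_reference_terms(cdm, encoder)
  out <- lapply(seq_len(nrow(rows)), function(i) {
    nm <- rows$name[i]
    if (is.na(nm) || !nzchar(trimws(nm))) {
      return(match_result(
        input_name = as_chr(nm), input_description = rows$description[i],
        winner = NA_character_, probability = NA_real_,
        combined_score = NA_real_, status = "error", candidates = NULL
      ))
    }
    harmonize_variable(
      nm, rows$description[i], cdm, encoder, classifier, config,
      term_vectors = tv
    )
  })
  structure(out, class = "match_result_list")
}

format_candidates <- function(ranking) {
  if (is.null(ranking)) return("")
  paste(
    sprintf("%s:%.6f", ranking$entries$term_id, ranking$entries$distance),
    collapse = ";"
  )
}

#' @export
as.data.frame.match_result_list <- function(x, ...) {
  data.frame(
    input_variable = vapply(x, function(r) r$input_name, character(1)),
    input_description = vapply(x, function(r) r$input_description, character(1)),
    term_id = vapply(x, function(r) as_chr(r$winner), character(1)),
    probability = vapply(x, function(r) r$probability %||% NA_real_, numeric(1)),
    combined_score = vapply(x, function(r) r$combined_score %||% NA_real_, numeric(1)),
    status = vapply(x, function(r) r$status, character(1)),
    candidates = vapply(x, function(r) format_candidates(r$candidates), character(1)),
    stringsAsFactors = FALSE
  )
}
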
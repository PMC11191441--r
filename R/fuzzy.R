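#' Levenshtein edit distance
#'
#' Minimum number of single-character insertions, deletions and substitutions
#' transforming `a` into `b` (unit costs, per code point, case-sensitive).
#' Backed by [utils::adist()].
#'
#' @param a,b single strings (empty strings allowed).
#' @return non-negative integer count.
#' @export
#' @examples
#' levenshtein_distance("Lhippo_FS_adj", "Rhippo_FS_adj") # 1
#' levenshtein_distance("ptage", "age")                   # 2
levenshtein_distance <- function(a, b) {
  stopifnot(length(a) == 1L, length(b) == 1L)
  as.integer(utils::adist(a, b)[1L, 1L])
}

# Vectorized case-folded similarity of one name against many candidate names.
norm_sim_vec <- function(name, candidates) {
  if (length(candidates) == 0L) return(numeric(0))
  d <- drop(utils::adist(tolower(name), tolower(candidates)))
  ml <- pmax(nchar(name), nchar(candidates))
  ifelse(ml == 0L, 1, 1 - d / ml)
}

#' Normalized string similarity
#'
#' `1 - levenshtein(lower(a), lower(b)) / max(nchar(a), nchar(b))`, defined as
#' 1 when both strings are empty. Equals 1 exactly when the case-folded
#' strings are equal, and 0 when one string is empty and the other is not.
#'
#' @param a,b single strings.
#' @return similarity in `[0, 1]`.
#' @export
#' @examples
#' normalized_similarity("age", "AGE")                        # 1
#' normalized_similarity("Lhippo_FS_adj", "Rhippo_FS_adj")    # 12/13
normalized_similarity <- function(a, b) {
  stopifnot(length(a) == 1L, length(b) == 1L)
  norm_sim_vec(a, b)
}

#' Blend classifier probability and string similarity
#'
#' The final ranking score of the cascade: `w1 * p_model + w2 * s_string`,
#' monotone nondecreasing in every argument. The weights let users run the
#' semantic model alone (`w1 = 1, w2 = 0`), string matching alone
#' (`w1 = 0, w2 = 1`) or any blend.
#'
#' @param p_model classifier match probability/probabilities in `[0, 1]`.
#' @param s_string normalized string similarity/similarities in `[0, 1]`.
#' @param w1,w2 weights in `[0, 1]`.
#' @return numeric combined score(s).
#' @export
combine_scores <- function(p_model, s_string, w1, w2) {
  if (!is_prob(w1) || !is_prob(w2)) abort_argument("weights must lie in [0, 1]")
  if (any(!is.finite(p_model)) || any(p_model < 0) || any(p_model > 1)) {
    abort_argument("p_model must lie in [0, 1]")
  }
  if (any(!is.finite(s_string)) || any(s_string < 0) || any(s_string > 1)) {
    abort_argument("s_string must lie in [0, 1]")
  }
  w1 * p_model + w2 * s_string
}

#' String-matching baseline harmonizer
#'
#' The naive comparator the cascade is evaluated against: the winner is the
#' reference term whose name (or, with `use_aliases`, any mapped variable
#' name, resolved to its parent term) maximizes [normalized_similarity()] with
#' the query name. Ties break to the lexicographically smaller term_id. Never
#' returns a no-match.
#'
#' @param name query variable name (non-empty); descriptions are ignored.
#' @param cdm a [new_cdm()] object with at least one term.
#' @param use_aliases also compare against mapped variable names.
#' @return A `match_result` (see [harmonize_variable()]) with
#'   `combined_score` set to the winning similarity and no probability.
#' @export
string_match_baseline <- function(name, cdm, use_aliases = FALSE) {
  if (length(name) != 1L || is.na(name) || !nzchar(trimws(name))) {
    abort_argument("query name must be non-empty")
  }
  if (nrow(cdm$terms) == 0L) abort_state("CDM contains no reference terms")
  cand <- data.frame(
    match_name = cdm$terms$name, term_id = cdm$terms$term_id,
    stringsAsFactors = FALSE
  )
  if (use_aliases && nrow(cdm$variables)) {
    cand <- rbind(cand, data.frame(
      match_name = cdm$variables$name, term_id = cdm$variables$term_id,
      stringsAsFactors = FALSE
    ))
  }
  sims <- norm_sim_vec(name, cand$match_name)
  best <- radix_order(-sims, cand$term_id, cand$match_name)[1L]
  match_result(
    input_name = name, input_description = "",
    winner = cand$term_id[best], probability = NA_real_,
    combined_score = sims[best], status = "matched", candidates = NULL
  )
}
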
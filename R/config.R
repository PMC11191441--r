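#' Harmonization configuration
#'
#' Bundles the tunable parameters of the inference cascade.
#'
#' @param K number of nearest reference terms retrieved in the embedding space
#'   (default 5, a sufficient standard at CDM scale).
#' @param w1 weight of the pairwise classifier probability in the combined
#'   score, in `[0, 1]` (default 1.0).
#' @param w2 weight of the normalized Levenshtein string similarity, in
#'   `[0, 1]` (default 0.0). `w1 + w2` is deliberately not forced to 1.
#' @param threshold elimination threshold on the raw classifier probability,
#'   in `[0, 1]` (default 0.5): candidates scoring below it are removed before
#'   the weighted blend picks a winner.
#' @param use_prior_knowledge expand retrieved candidates with every variable
#'   already mapped onto them (default `FALSE`); a winning alias is resolved
#'   back to its parent reference term.
#' @param seed integer seed driving every random choice downstream.
#' @param embedding_dim dimension of the shared embedding space (default 768).
#'
#' @return A list of class `harmonization_config`.
#' @export
harmonization_config <- function(K = 5L, w1 = 1.0, w2 = 0.0, threshold = 0.5,
                                 use_prior_knowledge = FALSE, seed = 1L,
                                 embedding_dim = 768L) {
  if (!is_count(K)) abort_argument("K must be a positive integer")
  if (!is_prob(w1)) abort_argument("w1 must lie in [0, 1]")
  if (!is_prob(w2)) abort_argument("w2 must lie in [0, 1]")
  if (!is_prob(threshold)) abort_argument("threshold must lie in [0, 1]")
  if (!is_count(embedding_dim)) abort_argument("embedding_dim must be a positive integer")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort_argument("seed must be a single integer")
  }
  structure(
    list(
      K = as.integer(K), w1 = w1, w2 = w2, threshold = threshold,
      use_prior_knowledge = isTRUE(use_prior_knowledge),
      seed = as.integer(seed), embedding_dim = as.integer(embedding_dim)
    ),
    class = "harmonization_config"
  )
}

#' @export
print.harmonization_config <- function(x, ...) {
  cat(sprintf(
    "<harmonization_config> K=%d w1=%g w2=%g threshold=%g prior_knowledge=%s seed=%d dim=%d\n",
    x$K, x$w1, x$w2, x$threshold, x$use_prior_knowledge, x$seed, x$embedding_dim
  ))
  invisible(x)
}
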
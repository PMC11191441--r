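#' Train the embedding model (the retrieval model)
#'
#' Learns a diagonal re-weighting of the base encoder's embedding space so
#' that, in Euclidean distance, each mapped variable moves closer to its own
#' reference term than to other reference terms of the same modality. Training
#' minimizes a margin-based triplet loss on (alias, own term, same-modality
#' other term) triplets with squared Euclidean distances, by projected
#' full-batch gradient descent on the per-dimension scale vector. With
#' `epochs = 0` the returned encoder reproduces `init` exactly; the fit is
#' deterministic under `seed` (which only draws the negative term per
#' triplet).
#'
#' @param cdm a [new_cdm()] object; needs mapped variables under at least two
#'   reference terms.
#' @param init the base encoder supplying the initial vectors (e.g.
#'   [ngram_encoder()]).
#' @param epochs gradient steps (default 40).
#' @param learning_rate step size (default 0.5).
#' @param margin triplet margin on squared distances (default 1.0).
#' @param seed integer seed for negative sampling.
#' @return A fitted encoder (base encoder plus learned scale) usable wherever
#'   `init` was; its training-loss trace is attached as attribute `history`.
#' @export
train_embedder <- function(cdm, init, epochs = 40L, learning_rate = 0.5,
                           margin = 1.0, seed = 1L) {
  validate_cdm(cdm)
  vars <- cdm$variables
  terms <- cdm$terms
  if (length(unique(vars$term_id)) < 2L) {
    abort_training("embedder training requires variables mapped to at least two reference terms")
  }
  d <- encoder_dimension(init)
  ts <- term_sentences(cdm)

  # one triplet per mapped variable; negative = random other term, same
  # modality when possible
  neg_id <- with_seed(seed, vapply(seq_len(nrow(vars)), function(i) {
    own <- vars$term_id[i]
    pool <- terms$term_id[terms$modality == vars$modality[i] & terms$term_id != own]
    if (length(pool) == 0L) pool <- terms$term_id[terms$term_id != own]
    pool[sample.int(length(pool), 1L)]
  }, character(1)))

  anchors <- build_sentence(vars$name, vars$description)
  a <- encode_text(init, anchors)
  p <- encode_text(init, unname(ts[vars$term_id]))
  q <- encode_text(init, unname(ts[neg_id]))
  d_own <- (a - p)^2
  d_oth <- (a - q)^2
  n <- nrow(d_own)

  s <- rep(1, d)
  history <- numeric(0)
  for (epoch in seq_len(epochs)) {
    s2 <- s^2
    slack <- margin + drop(d_own %*% s2) - drop(d_oth %*% s2)
    active <- slack > 0
    history <- c(history, mean(pmax(slack, 0)))
    if (!any(active)) break
    grad <- (2 * s) * (colSums(d_own[active, , drop = FALSE]) -
                         colSums(d_oth[active, , drop = FALSE])) / n
    s <- pmax(s - learning_rate * grad, 0)
  }

  out <- structure(
    list(base = init, scale = s),
    class = c("scaled_encoder", "text_encoder")
  )
  attr(out, "history") <- history
  out
}

#' Mean own-term vs other-term distance margin of an encoder
#'
#' Diagnostic for [train_embedder()]: over labeled items, the mean Euclidean
#' distance from each item to a same-modality *other* reference term minus the
#' mean distance to its *own* term. Positive margins mean retrieval pulls the
#' right term closer.
#'
#' @param encoder an encoder.
#' @param cdm the CDM providing the reference terms.
#' @param items data.frame with columns `name`, `description`, `term_id`
#'   (defaults to the CDM's own variables).
#' @param seed seed for drawing the comparison terms.
#' @return numeric margin (mean other-term distance minus mean own-term
#'   distance).
#' @export
embedding_margin <- function(encoder, cdm, items = NULL, seed = 1L) {
  if (is.null(items)) {
    items <- data.frame(
      name = cdm$variables$name, description = cdm$variables$description,
      term_id = cdm$variables$term_id, stringsAsFactors = FALSE
    )
  }
  terms <- cdm$terms
  ts <- term_sentences(cdm)
  mod <- terms$modality[match(items$term_id, terms$term_id)]
  neg_id <- with_seed(seed, vapply(seq_len(nrow(items)), function(i) {
    pool <- terms$term_id[terms$modality == mod[i] & terms$term_id != items$term_id[i]]
    if (length(pool) == 0L) pool <- terms$term_id[terms$term_id != items$term_id[i]]
    pool[sample.int(length(pool), 1L)]
  }, character(1)))
  a <- encode_text(encoder, build_sentence(items$name, items$description))
  p <- encode_text(encoder, unname(ts[items$term_id]))
  q <- encode_text(encoder, unname(ts[neg_id]))
  mean(sqrt(rowSums((a - q)^2))) - mean(sqrt(rowSums((a - p)^2)))
}
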
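# Pairwise features of two sentence embeddings: intercept, elementwise
# absolute difference, elementwise product.
pair_features <- function(a, b) {
  cbind(1, abs(a - b), a * b)
}

weighted_logloss <- function(p, y, w) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  mean(w * -(y * log(p) + (1 - y) * log(1 - p)))
}

#' Train the pairwise match classifier (the reranking model)
#'
#' Fits a weighted logistic model on the `[1, |a-b|, a*b]` features of the two
#' sentence embeddings — the offline analogue of a feed-forward classification
#' head over a pair encoder. Training is full-batch gradient descent with
#' backtracking step halving, so the weighted training loss is never above its
#' value at initialization, and the whole fit is deterministic (zero
#' initialization, no RNG). Per-pair class weights from
#' [assign_class_weights()] enter the loss directly.
#'
#' @param split a [split_dataset()] result (its `train` part is used) or a
#'   plain data.frame of labeled pairs.
#' @param encoder a fitted encoder; it is stored inside the classifier and
#'   used to embed sentences at scoring time.
#' @param epochs gradient steps (default 150; 0 returns the untrained model,
#'   which scores every pair 0.5).
#' @param learning_rate initial step size (default 8; backtracking step
#'   halving guards each update).
#' @return An object of class `pair_classifier`; score pairs with
#'   [pair_scores()].
#' @export
train_pair_classifier <- function(split, encoder, epochs = 150L, learning_rate = 8) {
  train <- if (inherits(split, "dataset_split")) split$train else split
  if (is.null(train) || nrow(train) == 0L) {
    abort_training("training set is empty")
  }
  if (length(unique(train$label)) < 2L) {
    abort_training("training data must contain both classes (labels 0 and 1)")
  }
  sents <- unique(c(train$sentence_a, train$sentence_b))
  m <- encode_text(encoder, sents)
  a <- m[match(train$sentence_a, sents), , drop = FALSE]
  b <- m[match(train$sentence_b, sents), , drop = FALSE]
  x <- pair_features(a, b)
  y <- as.numeric(train$label)
  wt <- as.numeric(train$weight)
  n <- nrow(x)

  w <- numeric(ncol(x))
  lr <- learning_rate
  cur <- weighted_logloss(stats::plogis(drop(x %*% w)), y, wt)
  history <- cur
  for (epoch in seq_len(epochs)) {
    p <- stats::plogis(drop(x %*% w))
    g <- drop(crossprod(x, wt * (p - y))) / n
    improved <- FALSE
    for (try in seq_len(30L)) {
      w_new <- w - lr * g
      l_new <- weighted_logloss(stats::plogis(drop(x %*% w_new)), y, wt)
      if (l_new <= cur) {
        w <- w_new
        cur <- l_new
        improved <- TRUE
        # let the step size recover after a successful step
        lr <- min(lr * 2, learning_rate)
        break
      }
      lr <- lr / 2
    }
    history <- c(history, cur)
    if (!improved) break
  }

  structure(
    list(
      weights = w, encoder = encoder, history = history,
      n_train = n, version = "1.0"
    ),
    class = c("ngram_pair_classifier", "pair_classifier")
  )
}

#' Score sentence pairs with a match classifier
#'
#' @param classifier a [train_pair_classifier()] or
#'   [manual_pair_classifier()] object.
#' @param query_sentence a single sentence.
#' @param sentences candidate sentences to pair the query with.
#' @return numeric vector of match probabilities in `[0, 1]`, one per
#'   candidate sentence; deterministic for a fixed fitted state.
#' @export
pair_scores <- function(classifier, query_sentence, sentences) {
  UseMethod("pair_scores")
}

#' @export
pair_scores.ngram_pair_classifier <- function(classifier, query_sentence, sentences) {
  stopifnot(length(query_sentence) == 1L)
  if (length(sentences) == 0L) return(numeric(0))
  enc <- classifier$encoder
  a <- encode_text(enc, query_sentence)
  b <- encode_text(enc, sentences)
  x <- pair_features(a[rep(1L, nrow(b)), , drop = FALSE], b)
  as.numeric(stats::plogis(drop(x %*% classifier$weights)))
}

#' Wrap an arbitrary pair-scoring function as a classifier
#'
#' Plug-in point for external rerankers (e.g. a fine-tuned transformer
#' cross-encoder): any function mapping two sentences to a probability obeys
#' the same contract as the built-in classifier.
#'
#' @param score_fun `function(sentence_a, sentence_b)` returning a single
#'   value in `[0, 1]`.
#' @return An object of class `pair_classifier`.
#' @export
manual_pair_classifier <- function(score_fun) {
  if (!is.function(score_fun)) abort_argument("score_fun must be a function")
  structure(
    list(score_fun = score_fun, version = "1.0"),
    class = c("manual_pair_classifier", "pair_classifier")
  )
}

#' @export
pair_scores.manual_pair_classifier <- function(classifier, query_sentence, sentences) {
  stopifnot(length(query_sentence) == 1L)
  p <- vapply(sentences, function(s) classifier$score_fun(query_sentence, s),
              numeric(1), USE.NAMES = FALSE)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort_state("pair classifier produced probabilities outside [0, 1]")
  }
  p
}

#' Score a single sentence pair
#'
#' @inheritParams pair_scores
#' @param sentence_a,sentence_b the two sentences.
#' @return match probability in `[0, 1]`.
#' @export
pair_score <- function(classifier, sentence_a, sentence_b) {
  pair_scores(classifier, sentence_a, sentence_b)[1L]
}

#' @export
print.pair_classifier <- function(x, ...) {
  cat(sprintf(
    "<pair_classifier> trained on %s pairs, final weighted loss %s\n",
    x$n_train %||% "?",
    if (!is.null(x$history)) format(utils::tail(x$history, 1), digits = 4) else "?"
  ))
  invisible(x)
}
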
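#' Train the full harmonization pipeline from a CDM
#'
#' Convenience orchestration of the training workflow: fit the embedder on the
#' CDM's curated mappings (when at least two terms have mapped variables),
#' build the labeled pair set (positives from the mapping edges, an equal
#' number of within-modality hard negatives capped by availability), weight
#' the classes, split train/test/validation, and fit the pairwise match
#' classifier on the training part. Everything is keyed to `config$seed`.
#'
#' @param cdm a [new_cdm()] object with mapped variables.
#' @param config a [harmonization_config()].
#' @param positive_mode passed to [generate_positive_pairs()].
#' @param fractions passed to [split_dataset()] (default 80/4/16).
#' @param w_neg,w_pos class weights (defaults 0.1 / 0.9).
#' @param embedder_epochs,classifier_epochs training lengths.
#' @return A list of class `harmonization_pipeline` with elements `encoder`,
#'   `classifier`, `term_vectors`, `cdm`, `config` and `split`.
#' @export
train_pipeline <- function(cdm, config = harmonization_config(),
                           positive_mode = "all_combinations",
                           fractions = c(0.80, 0.04, 0.16),
                           w_neg = 0.1, w_pos = 0.9,
                           embedder_epochs = 40L, classifier_epochs = 150L) {
  validate_cdm(cdm)
  base <- ngram_encoder(config$embedding_dim, config$seed)
  encoder <- if (length(unique(cdm$variables$term_id)) >= 2L) {
    train_embedder(cdm, base, epochs = embedder_epochs, seed = config$seed)
  } else {
    base
  }

  pos <- generate_positive_pairs(cdm, positive_mode)
  if (nrow(pos) == 0L) abort_training("CDM has no mapped variables to train on")
  pools <- negative_pair_pool(cdm)
  capacity <- sum(vapply(pools, nrow, integer(1)))
  neg <- generate_negative_pairs(cdm, min(nrow(pos), capacity), seed = config$seed)
  pairs <- assign_class_weights(rbind(pos, neg), w_neg = w_neg, w_pos = w_pos)
  split <- split_dataset(pairs, fractions, seed = config$seed)
  train <- if (length(unique(split$train$label)) < 2L) pairs else split
  classifier <- train_pair_classifier(train, encoder, epochs = classifier_epochs)

  structure(
    list(
      encoder = encoder, classifier = classifier,
      term_vectors = embed_reference_terms(cdm, encoder),
      cdm = cdm, config = config, split = split
    ),
    class = "harmonization_pipeline"
  )
}

#' @export
print.harmonization_pipeline <- function(x, ...) {
  cat(sprintf(
    "<harmonization_pipeline> %d reference terms, encoder dim %d, %d training pairs\n",
    nrow(x$cdm$terms), encoder_dimension(x$encoder), x$classifier$n_train
  ))
  invisible(x)
}

#' Save / load a fitted pipeline archive
#'
#' Serializes the fitted encoder, classifier, reference-term embeddings and
#' CDM into a single versioned archive file.
#'
#' @param pipeline a [train_pipeline()] object.
#' @param path archive file path (RDS).
#' @return `save_pipeline()`: `path`, invisibly. `load_pipeline()`: the
#'   restored pipeline.
#' @export
save_pipeline <- function(pipeline, path) {
  if (!inherits(pipeline, "harmonization_pipeline")) {
    abort_argument("not a harmonization_pipeline")
  }
  saveRDS(list(archive_version = "1.0", pipeline = pipeline), path)
  invisible(path)
}

#' @rdname save_pipeline
#' @export
load_pipeline <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("pipeline archive not found: %s", path))
  obj <- readRDS(path)
  if (!identical(obj$archive_version, "1.0") ||
      !inherits(obj$pipeline, "harmonization_pipeline")) {
    abort_format("not a cohortmapr pipeline archive")
  }
  obj$pipeline
}
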
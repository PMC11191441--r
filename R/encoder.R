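#' Build the sentence fed to the encoder and pair classifier
#'
#' A variable and its description are concatenated into one sentence,
#' `"<name> <description>"`, separated by a single space. Whitespace-only
#' descriptions are treated as absent, leaving the name unchanged.
#'
#' @param name variable or reference-term name(s); must be non-empty.
#' @param description matching description(s); `""` or whitespace for none.
#' @return character vector of sentences.
#' @export
#' @examples
#' build_sentence("MMSE", "Mini mental state exam total")
#' build_sentence("CDRSB", "")
build_sentence <- function(name, description = "") {
  name <- as_chr(name)
  description <- as_chr(description)
  if (length(description) == 1L && length(name) > 1L) {
    description <- rep(description, length(name))
  }
  if (length(name) != length(description)) {
    abort_argument("name and description must have matching lengths")
  }
  if (any(!nzchar(trimws(name)))) abort_argument("variable name must be non-empty")
  has_desc <- nzchar(trimws(description))
  ifelse(has_desc, paste(name, description), name)
}

#' Hashed character n-gram text encoder
#'
#' The package's default, fully offline embedding backend: the character
#' 3-gram multiset of the lowercased text (padded with `^`/`$` boundary
#' markers) is hashed into `dimension` buckets and L2-normalized. Identical
#' texts always yield identical vectors; the bucket assignment is a pure
#' function of `(dimension, seed)`. Any backend obeying the same contract —
#' `encode_text()` returns one finite, fixed-dimension row per input text —
#' can replace it, e.g. a mean-pooled transformer encoder wrapped with
#' [manual_encoder()].
#'
#' @param dimension embedding dimension d (default 768).
#' @param seed integer keying the hash function.
#' @return An encoder object usable with [encode_text()],
#'   [embed_reference_terms()], [train_embedder()] and
#'   [train_pair_classifier()].
#' @export
ngram_encoder <- function(dimension = 768L, seed = 1L) {
  if (!is_count(dimension)) abort_argument("dimension must be a positive integer")
  structure(
    list(
      dimension = as.integer(dimension),
      seed = as.integer(seed),
      cache = new.env(parent = emptyenv())
    ),
    class = c("ngram_encoder", "text_encoder")
  )
}

#' Wrap an arbitrary embedding function as an encoder
#'
#' @param encode_fun function taking one text and returning a numeric vector
#'   of length `dimension` with finite entries.
#' @param dimension embedding dimension the function guarantees.
#' @return An encoder object for use anywhere an [ngram_encoder()] fits.
#' @export
manual_encoder <- function(encode_fun, dimension) {
  if (!is.function(encode_fun)) abort_argument("encode_fun must be a function")
  if (!is_count(dimension)) abort_argument("dimension must be a positive integer")
  structure(
    list(encode_fun = encode_fun, dimension = as.integer(dimension)),
    class = c("manual_encoder", "text_encoder")
  )
}

#' Embed texts into the encoder's vector space
#'
#' @param encoder an encoder ([ngram_encoder()], [manual_encoder()], or the
#'   output of [train_embedder()]).
#' @param texts character vector of non-empty texts.
#' @return numeric matrix, one row per text, `encoder_dimension(encoder)`
#'   columns.
#' @export
encode_text <- function(encoder, texts) UseMethod("encode_text")

#' @export
encode_text.ngram_encoder <- function(encoder, texts) {
  texts <- as.character(texts)
  if (length(texts) == 0L) {
    return(matrix(numeric(0), nrow = 0L, ncol = encoder$dimension))
  }
  if (anyNA(texts) || any(!nzchar(texts))) {
    abort_argument("cannot encode empty text")
  }
  d <- encoder$dimension
  uniq <- unique(texts)
  um <- matrix(0, nrow = length(uniq), ncol = d)
  for (i in seq_along(uniq)) {
    um[i, ] <- ngram_vector(uniq[i], encoder)
  }
  um[match(texts, uniq), , drop = FALSE]
}

ngram_vector <- function(text, encoder) {
  d <- encoder$dimension
  padded <- paste0("^", tolower(text), "$")
  n <- nchar(padded)
  grams <- substring(padded, 1:(n - 2L), 3:n)
  cache <- encoder$cache
  buckets <- vapply(grams, function(g) {
    b <- cache[[g]]
    if (is.null(b)) {
      b <- hash_gram(g, d, encoder$seed)
      cache[[g]] <- b
    }
    b
  }, integer(1), USE.NAMES = FALSE)
  v <- tabulate(buckets, nbins = d)
  v / sqrt(sum(v * v))
}

# Deterministic polynomial rolling hash over code points; arithmetic stays
# below 2^53 so the double-precision modulo is exact.
hash_gram <- function(gram, d, seed) {
  h <- seed %% 2147483647
  for (code in utf8ToInt(gram)) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h %% d) + 1L
}

#' @export
encode_text.manual_encoder <- function(encoder, texts) {
  texts <- as.character(texts)
  if (anyNA(texts) || any(!nzchar(texts))) abort_argument("cannot encode empty text")
  out <- t(vapply(texts, encoder$encode_fun, numeric(encoder$dimension),
                  USE.NAMES = FALSE))
  if (any(!is.finite(out))) abort_state("encoder produced non-finite values")
  out
}

# Diagonal feature re-weighting learned by train_embedder(), applied on top of
# any base encoder.
#' @export
encode_text.scaled_encoder <- function(encoder, texts) {
  base <- encode_text(encoder$base, texts)
  sweep(base, 2L, encoder$scale, "*")
}

#' Dimension of an encoder's embedding space
#' @param encoder an encoder object.
#' @return integer dimension.
#' @export
encoder_dimension <- function(encoder) {
  if (!is.null(encoder$dimension)) return(encoder$dimension)
  if (inherits(encoder, "scaled_encoder")) return(encoder_dimension(encoder$base))
  abort_argument("not an encoder object")
}

#' Embed a single text with the default offline encoder
#'
#' Convenience wrapper: `baseline_encode(x, d, seed)` equals
#' `encode_text(ngram_encoder(d, seed), x)`.
#'
#' @param text a single non-empty text.
#' @param dimension embedding dimension (default 768).
#' @param seed hash seed (default 1).
#' @return numeric vector of length `dimension`, unit L2 norm.
#' @export
#' @examples
#' v <- baseline_encode("age", dimension = 64)
#' sum(v^2)
baseline_encode <- function(text, dimension = 768L, seed = 1L) {
  drop(encode_text(ngram_encoder(dimension, seed), text))
}

#' Embed every reference term of a CDM
#'
#' Builds one sentence per reference term from its name and description (see
#' [build_sentence()]) and encodes it. The returned matrix is the retrieval
#' index used by [get_candidates()]; its rownames are term identifiers and it
#' carries the term names/sentences as attributes so downstream scoring can
#' reuse them.
#'
#' @param cdm a [new_cdm()] object.
#' @param encoder a fitted encoder.
#' @return numeric matrix (terms x dimension) with `term_id` rownames.
#' @export
embed_reference_terms <- function(cdm, encoder) {
  terms <- cdm$terms
  if (nrow(terms) == 0L) abort_state("CDM contains no reference terms")
  sentences <- build_sentence(terms$name, terms$description)
  m <- encode_text(encoder, sentences)
  rownames(m) <- terms$term_id
  attr(m, "term_name") <- terms$name
  attr(m, "term_sentence") <- sentences
  m
}
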
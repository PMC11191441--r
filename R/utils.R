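`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library calls never clobber user randomness.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Locale-independent (C collation) ordering; used everywhere determinism across
# sessions matters.
radix_order <- function(...) order(..., method = "radix")

sort_chr <- function(x) sort(x, method = "radix")

sort_df <- function(df, cols) {
  o <- do.call(radix_order, unname(df[cols]))
  out <- df[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Canonical unordered form of string pairs using radix (C-locale) ranks, so that
# (a, b) and (b, a) collapse to one key irrespective of the session locale.
canonical_pairs <- function(a, b) {
  lv <- sort_chr(unique(c(a, b)))
  swap <- match(a, lv) > match(b, lv)
  data.frame(
    first  = ifelse(swap, b, a),
    second = ifelse(swap, a, b),
    stringsAsFactors = FALSE
  )
}

# Collision-safe composite key for (field, field) identity checks.
key2 <- function(a, b) paste(a, b, sep = "\u001f")

pair_key <- function(a, b) {
  cp <- canonical_pairs(a, b)
  paste(cp$first, cp$second, sep = "\u001f")
}

as_chr <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x
}

# A bare "-", en dash or em dash field means "no description" in cohort data
# dictionaries; readers map those to the empty string.
blank_dash <- function(x) {
  x <- as_chr(x)
  x[trimws(x) %in% c("-", "\u2013", "\u2014")] <- ""
  x
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == as.integer(x)
}

is_prob <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x <= 1
}
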
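#' Construct a common data model (CDM) object
#'
#' A CDM holds the curated reference terms of a harmonization target together
#' with the cohort variables already mapped onto them. Each cohort variable
#' maps to exactly one reference term (many-to-one); the set of variables
#' mapped to a term forms that term's alias set, which inference can use as
#' prior knowledge.
#'
#' @param terms data.frame with columns `term_id`, `name` and optionally
#'   `description`, `ontology_id`, `modality` (missing optional columns are
#'   filled with empty strings). One row per reference term.
#' @param variables data.frame with columns `name`, `source_id`, `term_id` and
#'   optionally `description`; one row per mapped cohort variable. `NULL` for a
#'   CDM holding reference terms only.
#' @param validate run [validate_cdm()] on the result (default `TRUE`).
#'
#' @return An object of class `cdm`: a list with data.frames `terms` (columns
#'   `term_id`, `name`, `description`, `ontology_id`, `modality`, sorted by
#'   `term_id`) and `variables` (columns `name`, `description`, `source_id`,
#'   `term_id`, `modality`, sorted by `source_id` then `name`). The mapping
#'   edges are the `term_id` column of `variables`.
#' @export
#' @examples
#' cdm <- new_cdm(
#'   terms = data.frame(term_id = "T1", name = "Age", modality = "Demographics"),
#'   variables = data.frame(
#'     name = c("age", "PTAGE"), source_id = c("A", "B"), term_id = "T1"
#'   )
#' )
#' aliases_of(cdm, "T1")
new_cdm <- function(terms, variables = NULL, validate = TRUE) {
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  for (col in c("description", "ontology_id", "modality")) {
    if (!col %in% names(terms)) terms[[col]] <- ""
  }
  if (!all(c("term_id", "name") %in% names(terms))) {
    abort_format("terms require columns: term_id, name")
  }
  terms <- data.frame(
    term_id     = as_chr(terms$term_id),
    name        = as_chr(terms$name),
    description = as_chr(terms$description),
    ontology_id = as_chr(terms$ontology_id),
    modality    = as_chr(terms$modality),
    stringsAsFactors = FALSE
  )
  terms <- sort_df(terms, "term_id")

  if (is.null(variables) || NROW(variables) == 0L) {
    variables <- data.frame(
      name = character(), description = character(), source_id = character(),
      term_id = character(), modality = character(), stringsAsFactors = FALSE
    )
  } else {
    variables <- as.data.frame(variables, stringsAsFactors = FALSE)
    if (!"description" %in% names(variables)) variables$description <- ""
    if (!all(c("name", "source_id", "term_id") %in% names(variables))) {
      abort_format("variables require columns: name, source_id, term_id")
    }
    variables <- data.frame(
      name        = as_chr(variables$name),
      description = as_chr(variables$description),
      source_id   = as_chr(variables$source_id),
      term_id     = as_chr(variables$term_id),
      modality    = as_chr(terms$modality[match(variables$term_id, terms$term_id)]),
      stringsAsFactors = FALSE
    )
    variables <- sort_df(variables, c("source_id", "name"))
  }

  cdm <- structure(list(terms = terms, variables = variables), class = "cdm")
  if (validate) validate_cdm(cdm)
  cdm
}

#' Validate a CDM against its structural invariants
#'
#' Checks that term identifiers are unique, names are non-empty, each
#' `(variable name, source_id)` pair occurs once, every mapping edge points at
#' an existing reference term, and each variable carries its term's modality.
#'
#' @param cdm a [new_cdm()] object.
#' @return `TRUE`, invisibly. Raises a classed error
#'   (`cohortmapr_format_error` / `cohortmapr_integrity_error`) otherwise.
#' @export
validate_cdm <- function(cdm) {
  if (!inherits(cdm, "cdm") || !is.list(cdm)) {
    abort_format("not a cdm object")
  }
  terms <- cdm$terms
  vars <- cdm$variables
  if (!all(c("term_id", "name", "description", "ontology_id", "modality") %in% names(terms))) {
    abort_format("terms table is missing required columns")
  }
  if (!all(c("name", "description", "source_id", "term_id", "modality") %in% names(vars))) {
    abort_format("variables table is missing required columns")
  }
  if (any(!nzchar(terms$term_id))) abort_integrity("empty term_id in terms table")
  if (any(!nzchar(terms$name))) abort_integrity("empty reference-term name")
  if (anyDuplicated(terms$term_id)) {
    abort_integrity(sprintf(
      "duplicate term_id: %s",
      paste(sort_chr(unique(terms$term_id[duplicated(terms$term_id)])), collapse = ", ")
    ))
  }
  if (nrow(vars)) {
    if (any(!nzchar(vars$name))) abort_integrity("empty variable name")
    key <- key2(vars$name, vars$source_id)
    if (anyDuplicated(key)) {
      dup <- vars[duplicated(key), , drop = FALSE][1L, ]
      abort_integrity(sprintf(
        "duplicate variable '%s' in source '%s'", dup$name, dup$source_id
      ))
    }
    unknown <- !vars$term_id %in% terms$term_id
    if (any(unknown)) {
      bad <- vars[unknown, , drop = FALSE][1L, ]
      abort_integrity(sprintf(
        "variable '%s' (source '%s') maps to unknown term_id '%s'",
        bad$name, bad$source_id, bad$term_id
      ))
    }
    tmod <- terms$modality[match(vars$term_id, terms$term_id)]
    if (any(vars$modality != tmod)) {
      bad <- which(vars$modality != tmod)[1L]
      abort_integrity(sprintf(
        "variable '%s' has modality '%s' but its term '%s' has '%s'",
        vars$name[bad], vars$modality[bad], vars$term_id[bad], tmod[bad]
      ))
    }
  }
  invisible(TRUE)
}

#' @export
print.cdm <- function(x, ...) {
  cat(sprintf(
    "<cdm> %d reference terms, %d mapped variables, %d sources, %d modalities\n",
    nrow(x$terms), nrow(x$variables),
    length(unique(x$variables$source_id)), length(unique(x$terms$modality))
  ))
  invisible(x)
}

#' CDM accessors
#'
#' @param cdm a [new_cdm()] object.
#' @return `cdm_terms()` / `cdm_variables()` return the corresponding
#'   data.frame; `cdm_modalities()` the sorted set of modality labels.
#' @export
cdm_terms <- function(cdm) cdm$terms

#' @rdname cdm_terms
#' @export
cdm_variables <- function(cdm) cdm$variables

#' @rdname cdm_terms
#' @export
cdm_modalities <- function(cdm) sort_chr(unique(cdm$terms$modality))

#' Aliases (prior known mappings) of a reference term
#'
#' Returns every cohort variable mapped onto `term_id`, in deterministic
#' (source_id, name) order. During inference these aliases can enrich the
#' candidate set, and a winning alias is resolved back to its parent term.
#'
#' @param cdm a [new_cdm()] object.
#' @param term_id a reference-term identifier present in the CDM.
#' @return The matching rows of `cdm_variables(cdm)` (possibly zero rows).
#' @export
aliases_of <- function(cdm, term_id) {
  stopifnot(length(term_id) == 1L)
  if (!term_id %in% cdm$terms$term_id) {
    abort_lookup(sprintf("unknown term_id '%s'", term_id))
  }
  out <- cdm$variables[cdm$variables$term_id == term_id, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reverse a known mapping: the reference term of a cohort variable
#'
#' @param cdm a [new_cdm()] object.
#' @param variable_name variable name as registered in the CDM.
#' @param source_id cohort / external-CDM label the variable belongs to.
#' @return The one-row `terms` data.frame of the reference term the variable
#'   maps to.
#' @export
reference_of <- function(cdm, variable_name, source_id) {
  hit <- cdm$variables$name == variable_name & cdm$variables$source_id == source_id
  if (!any(hit)) {
    abort_lookup(sprintf(
      "no variable '%s' registered for source '%s'", variable_name, source_id
    ))
  }
  tid <- cdm$variables$term_id[which(hit)[1L]]
  out <- cdm$terms[cdm$terms$term_id == tid, , drop = FALSE]
  rownames(out) <- NULL
  out
}

cdm_csv_columns <- c(
  "term_id", "term_name", "term_description", "ontology_id", "modality",
  "variable_name", "variable_description", "source_id"
)

read_csv_verbatim <- function(path) {
  utils::read.csv(
    path, colClasses = "character", check.names = FALSE,
    na.strings = character(0), fileEncoding = "UTF-8"
  )
}

#' Read a CDM from disk
#'
#' Two serializations are supported: a long-format CSV (one row per mapped
#' variable with its term's columns repeated; term-only rows leave the
#' variable columns empty) and a lossless JSON format with separate `terms`,
#' `variables` and `mappings` arrays. A bare "-"/en-dash description is read
#' as "no description".
#'
#' @param path file path.
#' @param format `"auto"` (by file extension), `"csv"` or `"json"`.
#' @return A validated [new_cdm()] object.
#' @seealso [save_cdm()]
#' @export
load_cdm <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) abort_format(sprintf("CDM file not found: %s", path))
  if (format == "csv") load_cdm_csv(path) else load_cdm_json(path)
}

load_cdm_csv <- function(path) {
  df <- read_csv_verbatim(path)
  missing <- setdiff(cdm_csv_columns, names(df))
  if (length(missing)) {
    abort_format(sprintf("missing required column: %s", missing[1L]))
  }
  terms <- unique(data.frame(
    term_id     = df$term_id,
    name        = df$term_name,
    description = blank_dash(df$term_description),
    ontology_id = as_chr(df$ontology_id),
    modality    = as_chr(df$modality),
    stringsAsFactors = FALSE
  ))
  if (anyDuplicated(terms$term_id)) {
    dup <- terms$term_id[duplicated(terms$term_id)][1L]
    abort_integrity(sprintf("conflicting definitions for term_id '%s'", dup))
  }
  keep <- nzchar(as_chr(df$variable_name))
  variables <- if (any(keep)) {
    data.frame(
      name        = df$variable_name[keep],
      description = blank_dash(df$variable_description[keep]),
      source_id   = as_chr(df$source_id[keep]),
      term_id     = as_chr(df$term_id[keep]),
      stringsAsFactors = FALSE
    )
  } else NULL
  new_cdm(terms, variables)
}

json_df <- function(x, cols) {
  if (is.null(x) || length(x) == 0L) {
    x <- as.data.frame(
      stats::setNames(rep(list(character()), length(cols)), cols),
      stringsAsFactors = FALSE
    )
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  missing <- setdiff(cols, names(x))
  if (length(missing)) {
    abort_format(sprintf("missing required key: %s", missing[1L]))
  }
  x[cols]
}

load_cdm_json <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (key in c("terms", "variables", "mappings")) {
    if (!key %in% names(js)) abort_format(sprintf("missing required key: %s", key))
  }
  terms <- json_df(js$terms, c("term_id", "name", "description", "ontology_id", "modality"))
  terms$description <- blank_dash(terms$description)
  vars <- json_df(js$variables, c("name", "description", "source_id"))
  vars$description <- blank_dash(vars$description)
  maps <- json_df(js$mappings, c("variable_name", "source_id", "term_id"))

  vkey <- key2(vars$name, vars$source_id)
  mkey <- key2(maps$variable_name, maps$source_id)
  if (any(!mkey %in% vkey)) {
    abort_integrity(sprintf(
      "mapping references unknown variable '%s'",
      maps$variable_name[!mkey %in% vkey][1L]
    ))
  }
  idx <- match(vkey, mkey)
  if (anyNA(idx) && nrow(vars)) {
    abort_integrity(sprintf(
      "variable '%s' (source '%s') has no mapping",
      vars$name[is.na(idx)][1L], vars$source_id[is.na(idx)][1L]
    ))
  }
  variables <- if (nrow(vars)) {
    data.frame(
      name = vars$name, description = vars$description,
      source_id = vars$source_id, term_id = maps$term_id[idx],
      stringsAsFactors = FALSE
    )
  } else NULL
  new_cdm(terms, variables)
}

#' Write a CDM to disk
#'
#' JSON is the lossless master format (separate term / variable / mapping
#' arrays); the long-format CSV mirrors the data-dictionary world and repeats
#' the term columns on every variable row. Output row order is canonical, so
#' saving a loaded CDM reproduces the file byte-for-byte (JSON).
#'
#' @param cdm a [new_cdm()] object.
#' @param path output file path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
save_cdm <- function(cdm, path, format = c("json", "csv")) {
  format <- match.arg(format)
  validate_cdm(cdm)
  terms <- cdm$terms
  vars <- cdm$variables
  if (format == "json") {
    obj <- list(
      format_version = "1.0",
      terms = terms,
      variables = vars[c("name", "description", "source_id")],
      mappings = data.frame(
        variable_name = vars$name, source_id = vars$source_id,
        term_id = vars$term_id, stringsAsFactors = FALSE
      )
    )
    jsonlite::write_json(
      obj, path, dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  } else {
    rows <- merge(
      data.frame(
        term_id = terms$term_id, term_name = terms$name,
        term_description = terms$description, ontology_id = terms$ontology_id,
        modality = terms$modality, stringsAsFactors = FALSE
      ),
      data.frame(
        term_id = vars$term_id, variable_name = vars$name,
        variable_description = vars$description, source_id = vars$source_id,
        stringsAsFactors = FALSE
      ),
      by = "term_id", all.x = TRUE
    )
    for (col in c("variable_name", "variable_description", "source_id")) {
      rows[[col]] <- as_chr(rows[[col]])
    }
    rows <- sort_df(rows[cdm_csv_columns], c("term_id", "source_id", "variable_name"))
    utils::write.csv(rows, path, row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read a cohort data dictionary
#'
#' Expects a CSV with a `variable` column and an optional `description`
#' column (absent descriptions and bare dashes become empty strings).
#'
#' @param path CSV file path.
#' @return data.frame with columns `name` and `description`, in file order.
#' @export
load_dictionary <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("dictionary file not found: %s", path))
  df <- read_csv_verbatim(path)
  if (!"variable" %in% names(df)) {
    abort_format("missing required column: variable")
  }
  data.frame(
    name = as_chr(df$variable),
    description = if ("description" %in% names(df)) blank_dash(df$description) else
      character(nrow(df)),
    stringsAsFactors = FALSE
  )
}
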
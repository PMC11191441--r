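# Built-in concept vocabulary spanning the modalities of a dementia-cohort
# data landscape. Columns: name, abbrev, synonym, description, modality,
# lateral ("L" marks concepts that exist as left/right pairs).
concept_vocabulary <- function() {
  v <- rbind(
    c("Age", "AGE", "Age at Visit", "Age of the participant in years at the sampling visit", "Demographics", ""),
    c("Sex", "SEX", "Gender", "Biological sex of the participant", "Demographics", ""),
    c("Years of Education", "EDUC", "Education Years", "Total years of completed formal education", "Demographics", ""),
    c("Marital Status", "MARITAL", "Civil Status", "Marital status of the participant at baseline", "Demographics", ""),
    c("Handedness", "HAND", "Dominant Hand", "Dominant hand of the participant", "Demographics", ""),
    c("Ethnicity", "ETHNIC", "Ethnic Group", "Self reported ethnicity of the participant", "Demographics", ""),
    c("Height", "HT", "Body Height", "Standing body height in centimeters", "Demographics", ""),
    c("Weight", "WT", "Body Weight", "Body weight in kilograms", "Demographics", ""),
    c("Body Mass Index", "BMI", "Quetelet Index", "Body mass index computed as weight over squared height", "Demographics", ""),
    c("Smoking Status", "SMOKE", "Tobacco Use", "Current and past tobacco smoking status", "Demographics", ""),
    c("Mini Mental State Examination", "MMSE", "Folstein Test Score", "Total score of the mini mental state examination", "Cognition", ""),
    c("Montreal Cognitive Assessment", "MOCA", "MoCA Total", "Total score of the Montreal cognitive assessment", "Cognition", ""),
    c("Clinical Dementia Rating Sum of Boxes", "CDRSB", "CDR Sum of Boxes", "Sum of boxes score of the clinical dementia rating scale", "Cognition", ""),
    c("Alzheimer Disease Assessment Scale Cognitive Subscale", "ADAS", "ADAS Cog Total", "Total score of the cognitive subscale of the Alzheimer disease assessment scale", "Cognition", ""),
    c("Rey Auditory Verbal Learning Test Immediate Recall", "RAVLT", "AVLT Immediate", "Immediate recall score of the Rey auditory verbal learning test", "Cognition", ""),
    c("Logical Memory Delayed Recall", "LMDR", "Delayed Paragraph Recall", "Delayed recall score of the logical memory test", "Cognition", ""),
    c("Trail Making Test Part A", "TMTA", "Trails A Time", "Completion time in seconds for part A of the trail making test", "Cognition", ""),
    c("Trail Making Test Part B", "TMTB", "Trails B Time", "Completion time in seconds for part B of the trail making test", "Cognition", ""),
    c("Boston Naming Test", "BNT", "Naming Test Score", "Total score of the Boston naming test", "Cognition", ""),
    c("Category Fluency Animals", "CFA", "Animal Fluency", "Number of animals named in one minute", "Cognition", ""),
    c("Digit Span Forward", "DSF", "Forward Digit Span", "Longest sequence of digits repeated forward", "Cognition", ""),
    c("Geriatric Depression Scale", "GDS", "Depression Score", "Total score of the geriatric depression scale", "Cognition", ""),
    c("Clinical Diagnosis", "DX", "Diagnosis Group", "Clinical diagnosis of the participant at the visit", "Clinical", ""),
    c("Systolic Blood Pressure", "SBP", "Systolic BP", "Systolic blood pressure in millimeters of mercury", "Clinical", ""),
    c("Diastolic Blood Pressure", "DBP", "Diastolic BP", "Diastolic blood pressure in millimeters of mercury", "Clinical", ""),
    c("Heart Rate", "HR", "Pulse Rate", "Resting heart rate in beats per minute", "Clinical", ""),
    c("Fasting Glucose", "GLU", "Blood Glucose", "Fasting plasma glucose concentration", "Clinical", ""),
    c("Total Cholesterol", "CHOL", "Serum Cholesterol", "Total serum cholesterol concentration", "Clinical", ""),
    c("HDL Cholesterol", "HDL", "HDL Level", "High density lipoprotein cholesterol concentration", "Clinical", ""),
    c("LDL Cholesterol", "LDL", "LDL Level", "Low density lipoprotein cholesterol concentration", "Clinical", ""),
    c("Triglycerides", "TRIG", "Serum Triglycerides", "Serum triglyceride concentration", "Clinical", ""),
    c("Serum Creatinine", "CREAT", "Creatinine Level", "Serum creatinine concentration", "Clinical", ""),
    c("Hemoglobin A1c", "HBA1C", "Glycated Hemoglobin", "Glycated hemoglobin percentage", "Clinical", ""),
    c("Number of Medications", "NMED", "Medication Count", "Number of concurrent medications reported", "Clinical", ""),
    c("CSF Amyloid Beta 42", "ABETA42", "CSF AB42", "Concentration of amyloid beta 1 42 peptide in cerebrospinal fluid", "CSF", ""),
    c("CSF Amyloid Beta 40", "ABETA40", "CSF AB40", "Concentration of amyloid beta 1 40 peptide in cerebrospinal fluid", "CSF", ""),
    c("CSF Total Tau", "TTAU", "CSF Tau", "Concentration of total tau protein in cerebrospinal fluid", "CSF", ""),
    c("CSF Phosphorylated Tau 181", "PTAU", "CSF pTau", "Concentration of tau phosphorylated at threonine 181 in cerebrospinal fluid", "CSF", ""),
    c("CSF Neurofilament Light", "CSFNFL", "CSF NfL", "Concentration of neurofilament light chain in cerebrospinal fluid", "CSF", ""),
    c("Plasma Neurofilament Light", "PNFL", "Plasma NfL", "Concentration of neurofilament light chain in plasma", "CSF", ""),
    c("Plasma Amyloid Beta Ratio", "PABR", "Plasma AB Ratio", "Ratio of amyloid beta 42 to amyloid beta 40 in plasma", "CSF", ""),
    c("CSF Tau Amyloid Ratio", "ATR", "Tau Abeta Ratio", "Ratio of total tau to amyloid beta 42 in cerebrospinal fluid", "CSF", ""),
    c("APOE Genotype", "APOE", "Apolipoprotein E Genotype", "Apolipoprotein E allele pair of the participant", "Genetics", ""),
    c("APOE4 Carrier Status", "APOE4", "E4 Carrier", "Indicator for carrying at least one apolipoprotein E epsilon 4 allele", "Genetics", ""),
    c("Polygenic Risk Score", "PRS", "Genetic Risk Score", "Polygenic risk score for late onset Alzheimer disease", "Genetics", ""),
    c("Hippocampus Volume", "HIPPO", "Hippocampal Volume", "Volume of the hippocampus from structural imaging", "MRI", "L"),
    c("Entorhinal Cortex Thickness", "ENTORH", "Entorhinal Thickness", "Mean cortical thickness of the entorhinal cortex", "MRI", "L"),
    c("Amygdala Volume", "AMYG", "Amygdalar Volume", "Volume of the amygdala from structural imaging", "MRI", "L"),
    c("Lateral Ventricle Volume", "LVENT", "Ventricular Volume", "Volume of the lateral ventricle", "MRI", "L"),
    c("Middle Temporal Gyrus Volume", "MIDTEMP", "Mid Temporal Volume", "Volume of the middle temporal gyrus", "MRI", "L"),
    c("Fusiform Gyrus Volume", "FUSI", "Fusiform Volume", "Volume of the fusiform gyrus", "MRI", "L"),
    c("Precuneus Thickness", "PRECUN", "Precuneus Cortical Thickness", "Mean cortical thickness of the precuneus", "MRI", "L"),
    c("Caudate Volume", "CAUD", "Caudate Nucleus Volume", "Volume of the caudate nucleus", "MRI", "L"),
    c("Putamen Volume", "PUTA", "Putamen Nucleus Volume", "Volume of the putamen", "MRI", "L"),
    c("Thalamus Volume", "THAL", "Thalamic Volume", "Volume of the thalamus", "MRI", "L"),
    c("Total Intracranial Volume", "ICV", "Intracranial Volume", "Estimated total intracranial volume", "MRI", ""),
    c("White Matter Hyperintensity Volume", "WMH", "WMH Volume", "Total volume of white matter hyperintensities", "MRI", ""),
    c("Whole Brain Volume", "WBV", "Brain Volume", "Total brain volume from structural imaging", "MRI", ""),
    c("Gray Matter Volume", "GMV", "Grey Matter Volume", "Total gray matter volume", "MRI", ""),
    c("Amyloid PET Composite", "AMYPET", "Amyloid SUVR", "Composite standardized uptake value ratio from amyloid positron emission tomography", "PET", ""),
    c("Tau PET Meta ROI", "TAUPET", "Tau SUVR", "Standardized uptake value ratio in the temporal meta region from tau positron emission tomography", "PET", ""),
    c("FDG PET Composite", "FDG", "Glucose Metabolism SUVR", "Composite standardized uptake value ratio from fluorodeoxyglucose positron emission tomography", "PET", ""),
    c("Amyloid PET Status", "AMYSTAT", "Amyloid Positivity", "Binary amyloid positivity status from positron emission tomography", "PET", "")
  )
  data.frame(
    name = v[, 1], abbrev = v[, 2], synonym = v[, 3], description = v[, 4],
    modality = v[, 5], lateral = v[, 6] == "L", stringsAsFactors = FALSE
  )
}

# Visit/derivation qualifiers multiply the concept vocabulary into a larger
# term universe; qualified siblings of one concept make natural hard cases.
concept_qualifiers <- function() {
  data.frame(
    suffix = c("", " at Baseline", " at Month 12", " at Month 24",
               " Change from Baseline"),
    desc = c("", ", measured at the baseline visit",
             ", measured at the month 12 visit",
             ", measured at the month 24 visit",
             ", change relative to the baseline visit"),
    stringsAsFactors = FALSE
  )
}

default_variant_rules <- function() {
  c(
    abbreviate_initials = 0.25, truncate = 0.15, case_change = 0.70,
    underscore_style = 0.70, cohort_suffix = 0.20, vowel_drop = 0.15,
    synonym_swap = 0.20, drop_description = 0.30
  )
}

#' Specification for a synthetic CDM benchmark
#'
#' Describes the synthetic study conditions: how many reference terms, how
#' many training cohorts, which fraction of terms come as left/right
#' lateralized near-duplicate pairs, and the per-rule probabilities of the
#' naming-convention transforms each cohort applies to term names
#' (abbreviation to initials, truncation, case changes, underscore/camel
#' styling, cohort-specific suffixes, vowel dropping, synonym swaps, dropped
#' descriptions).
#'
#' @param n_terms number of reference terms (>= 2).
#' @param n_cohorts number of mapped training cohorts (>= 1).
#' @param modalities optional explicit modality labels; when supplied they are
#'   assigned round-robin over terms (lateralized pairs stay together in one
#'   modality). Default `NULL` keeps each concept's natural modality.
#' @param lateralized_fraction fraction of terms emitted as left/right pairs
#'   whose names differ by a single character (default 0.2).
#' @param rules named probabilities in `[0, 1]` for every variant rule; see
#'   `default_variant_rules()` in the package source for the defaults.
#' @param seed integer seed; all generation is reproducible under it.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_terms = 50L, n_cohorts = 3L, modalities = NULL,
                           lateralized_fraction = 0.2,
                           rules = default_variant_rules(), seed = 1L) {
  if (!is_count(n_terms) || n_terms < 2) abort_argument("n_terms must be >= 2")
  if (!is_count(n_cohorts)) abort_argument("n_cohorts must be >= 1")
  if (!is_prob(lateralized_fraction)) {
    abort_argument("lateralized_fraction must lie in [0, 1]")
  }
  need <- names(default_variant_rules())
  if (!all(need %in% names(rules))) {
    abort_argument(sprintf(
      "rules must name all of: %s", paste(need, collapse = ", ")
    ))
  }
  rules <- rules[need]
  if (any(!is.finite(rules)) || any(rules < 0) || any(rules > 1)) {
    abort_argument("rule probabilities must lie in [0, 1]")
  }
  structure(
    list(
      n_terms = as.integer(n_terms), n_cohorts = as.integer(n_cohorts),
      modalities = modalities, lateralized_fraction = lateralized_fraction,
      rules = rules, seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

#' Generate synthetic reference terms
#'
#' Draws `n_terms` reference terms from the built-in concept vocabulary
#' crossed with visit qualifiers. A `lateralized_fraction` of the terms is
#' emitted as left/right pairs whose names differ only in an `(L)`/`(R)`
#' marker — the hard-negative structure of lateralized imaging variables.
#' Deterministic under `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return data.frame of reference terms (CDM `terms` columns plus generator
#'   bookkeeping columns `entry`, `side`, `qualifier` consumed by
#'   [generate_cohort_variants()]).
#' @export
generate_reference_terms <- function(spec) {
  vocab <- concept_vocabulary()
  quals <- concept_qualifiers()
  n_pairs <- floor(spec$n_terms * spec$lateralized_fraction / 2)
  n_single <- spec$n_terms - 2L * n_pairs

  universe <- expand.grid(
    entry = seq_len(nrow(vocab)), qual = seq_len(nrow(quals)),
    KEEP.OUT.ATTRS = FALSE
  )
  lat_universe <- which(vocab$lateral[universe$entry])
  if (n_pairs > length(lat_universe)) {
    abort_argument("lateralized_fraction exceeds the lateralizable vocabulary")
  }
  if (spec$n_terms - 2L * n_pairs + n_pairs > nrow(universe)) {
    abort_argument("n_terms exceeds the synthetic vocabulary capacity")
  }

  with_seed(spec$seed, {
    lat_rows <- sample(lat_universe, n_pairs)
    single_pool <- setdiff(seq_len(nrow(universe)), lat_rows)
    single_rows <- sample(single_pool, n_single)

    units <- list()
    for (r in lat_rows) units[[length(units) + 1L]] <- c(row = r, lat = 1L)
    for (r in single_rows) units[[length(units) + 1L]] <- c(row = r, lat = 0L)
    units <- units[sample.int(length(units))]

    rows <- list()
    for (u in seq_along(units)) {
      r <- units[[u]]["row"]
      e <- universe$entry[r]
      q <- universe$qual[r]
      base_name <- paste0(vocab$name[e], quals$suffix[q])
      base_desc <- paste0(vocab$description[e], quals$desc[q])
      modality <- if (is.null(spec$modalities)) vocab$modality[e] else
        spec$modalities[((u - 1L) %% length(spec$modalities)) + 1L]
      if (units[[u]]["lat"] == 1L) {
        for (side in c("L", "R")) {
          word <- if (side == "L") "left" else "right"
          rows[[length(rows) + 1L]] <- data.frame(
            name = sprintf("%s (%s)", base_name, side),
            description = sprintf("%s, %s hemisphere", base_desc, word),
            modality = modality, entry = e, side = side,
            qualifier = q, stringsAsFactors = FALSE
          )
        }
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          name = base_name, description = base_desc, modality = modality,
          entry = e, side = "", qualifier = q, stringsAsFactors = FALSE
        )
      }
    }
    out <- do.call(rbind, rows)
    out$term_id <- sprintf("T%04d", seq_len(nrow(out)))
    out$ontology_id <- sprintf("SYN:%06d", seq_len(nrow(out)))
    rownames(out) <- NULL
    out[c("term_id", "name", "description", "ontology_id", "modality",
          "entry", "side", "qualifier")]
  })
}

# Cohort-level naming style, drawn once per cohort: how the cohort cases its
# names, joins words and marks laterality.
draw_cohort_style <- function() {
  list(
    case = sample(c("upper", "lower", "title"), 1L),
    sep = sample(c("_", ""), 1L),
    side_style = sample(c("prefix", "suffix"), 1L)
  )
}

apply_case <- function(x, style) {
  switch(style,
    upper = toupper(x),
    lower = tolower(x),
    title = x
  )
}

abbrev_initials <- function(phrase) {
  tokens <- strsplit(phrase, " ", fixed = TRUE)[[1]]
  paste(vapply(tokens, function(tk) {
    if (grepl("^[0-9]+$", tk)) tk else toupper(substr(tk, 1L, 1L))
  }, character(1)), collapse = "")
}

drop_vowels <- function(x) {
  out <- gsub("[aeiou]", "", x)
  ifelse(nzchar(out), out, x)
}

# One cohort-style variant of a reference term. Returns list(name, desc,
# fired) where fired records whether any name rule applied (the identity
# channel keeps the term name verbatim when nothing fires).
make_variant <- function(term, vocab, quals, style, rules) {
  fires <- stats::runif(length(rules)) < rules
  names(fires) <- names(rules)
  e <- term$entry
  q <- term$qualifier
  phrase <- paste0(vocab$name[e], quals$suffix[q])
  if (fires[["synonym_swap"]]) {
    syn <- sample(c(vocab$synonym[e], vocab$abbrev[e]), 1L)
    phrase <- paste0(syn, quals$suffix[q])
  }
  if (fires[["abbreviate_initials"]]) {
    phrase <- abbrev_initials(phrase)
  } else if (fires[["truncate"]]) {
    collapsed <- gsub(" ", "", phrase, fixed = TRUE)
    phrase <- substr(collapsed, 1L, max(4L, sample(5:8, 1L)))
  }
  if (fires[["underscore_style"]]) {
    phrase <- gsub(" ", style$sep, phrase, fixed = TRUE)
  }
  if (fires[["case_change"]]) {
    phrase <- apply_case(phrase, style$case)
  }
  if (nzchar(term$side)) {
    side <- if (fires[["case_change"]] && style$case == "lower")
      tolower(term$side) else term$side
    phrase <- if (style$side_style == "prefix")
      paste0(side, "_", phrase) else paste0(phrase, "_", side)
  }
  if (fires[["vowel_drop"]]) {
    phrase <- drop_vowels(phrase)
  }
  if (fires[["cohort_suffix"]]) {
    phrase <- paste0(phrase, "_", tolower(style$cohort_tag))
  }
  any_name_rule <- any(fires[c("synonym_swap", "abbreviate_initials", "truncate",
                               "underscore_style", "case_change", "vowel_drop",
                               "cohort_suffix")])
  name <- if (any_name_rule) phrase else term$name
  desc <- term$description
  if (fires[["drop_description"]]) {
    desc <- ""
  } else {
    if (fires[["case_change"]]) desc <- tolower(desc)
    if (fires[["truncate"]]) {
      words <- strsplit(desc, " ", fixed = TRUE)[[1]]
      desc <- paste(utils::head(words, 6L), collapse = " ")
    }
  }
  list(name = name, desc = desc)
}

variant_retry_cap <- 100L

# Generate one variant avoiding the names in `taken`; after the retry cap, a
# deterministic numeric suffix resolves the collision.
variant_avoiding <- function(term, vocab, quals, style, rules, taken) {
  for (i in seq_len(variant_retry_cap)) {
    v <- make_variant(term, vocab, quals, style, rules)
    if (!v$name %in% taken) return(v)
  }
  k <- 2L
  base <- v$name
  while (paste0(base, "_", k) %in% taken) k <- k + 1L
  v$name <- paste0(base, "_", k)
  v
}

#' Generate cohort variants of reference terms as a mapped CDM
#'
#' For each of `spec$n_cohorts` cohorts and each reference term, produces one
#' variant variable name via the spec's variant rules under a cohort-level
#' naming style (the way real cohorts apply one convention consistently), plus
#' a possibly dropped/rewritten description, and assembles everything into a
#' validated CDM with one mapping edge per variable. When no name rule fires,
#' the variant equals the term name verbatim. Deterministic under `spec$seed`.
#'
#' @param terms [generate_reference_terms()] output.
#' @param spec the matching [synthetic_spec()].
#' @return A [new_cdm()] object with `n_terms * n_cohorts` variables.
#' @export
generate_cohort_variants <- function(terms, spec) {
  if (NROW(terms) == 0L) abort_argument("terms must be non-empty")
  vocab <- concept_vocabulary()
  quals <- concept_qualifiers()
  with_seed(spec$seed + 1L, {
    vars <- list()
    for (c_idx in seq_len(spec$n_cohorts)) {
      cohort <- paste0("C", c_idx)
      style <- draw_cohort_style()
      style$cohort_tag <- cohort
      taken <- character(0)
      for (t_idx in seq_len(nrow(terms))) {
        term <- terms[t_idx, ]
        v <- variant_avoiding(term, vocab, quals, style, spec$rules, taken)
        taken <- c(taken, v$name)
        vars[[length(vars) + 1L]] <- data.frame(
          name = v$name, description = v$desc, source_id = cohort,
          term_id = term$term_id, stringsAsFactors = FALSE
        )
      }
    }
    new_cdm(
      terms[c("term_id", "name", "description", "ontology_id", "modality")],
      do.call(rbind, vars)
    )
  })
}

#' Generate an unseen labeled cohort for evaluation
#'
#' Produces one labeled variant per reference term under a fresh cohort style,
#' guaranteeing that no generated name collides with any variable name in
#' `exclude` (bounded retries, then deterministic suffixing) — the synthetic
#' analogue of harmonizing a cohort held out of training. Truth labels are
#' retained for scoring only.
#'
#' @param terms [generate_reference_terms()] output.
#' @param spec the matching [synthetic_spec()]; `spec$seed` drives this cohort
#'   (pass a derived seed for additional cohorts).
#' @param exclude the training CDM whose variable names must be avoided.
#' @param source_id label for the generated cohort (default `"UNSEEN"`).
#' @return data.frame with columns `name`, `description`, `term_id` (truth),
#'   one row per reference term.
#' @export
generate_unseen_cohort <- function(terms, spec, exclude, source_id = "UNSEEN") {
  validate_cdm(exclude)
  vocab <- concept_vocabulary()
  quals <- concept_qualifiers()
  with_seed(spec$seed + 2L, {
    style <- draw_cohort_style()
    style$cohort_tag <- source_id
    taken <- exclude$variables$name
    out <- list()
    for (t_idx in seq_len(nrow(terms))) {
      term <- terms[t_idx, ]
      v <- variant_avoiding(term, vocab, quals, style, spec$rules, taken)
      taken <- c(taken, v$name)
      out[[length(out) + 1L]] <- data.frame(
        name = v$name, description = v$desc, term_id = term$term_id,
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, out)
  })
}
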
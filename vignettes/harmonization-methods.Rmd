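---
title: "Methods: retrieve-and-rerank harmonization of cohort variables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: retrieve-and-rerank harmonization of cohort variables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The harmonization problem

A common data model (CDM) fixes a canonical set of *reference terms* — one
per measured concept, e.g. "Mini Mental State Examination" — and records, for
every participating cohort, which source variable maps onto which term. Once
a CDM exists, harmonizing a *new* cohort's data dictionary means assigning
each of its variables (a name, plus a description when the dictionary has
one) to a reference term, or declaring that no term fits. `cohortmapr`
automates that assignment. It operates purely on metadata: variable names and
descriptions, never participant-level values, so nothing privacy-sensitive is
touched.

## Model

Every item — reference term or cohort variable — is rendered as a sentence by
concatenating its name and description with a single space
(`build_sentence()`); a whitespace-only description leaves the name
unchanged. The cascade then has three stages.

**Stage 1, candidate retrieval.** An encoder maps sentences into a
fixed-dimension Euclidean space (`embedding_dim`, default 768). The query
sentence is embedded and the K nearest reference terms are retrieved by exact
scan (`get_candidates()`); approximate nearest-neighbour indexing is
deliberately out of scope, since CDMs hold on the order of 10³ terms and an
exact scan is both cheap and trivially correct. Distances tie-break to the
lexicographically smaller term identifier so rankings are total orders.

**Stage 2, pairwise reranking.** A binary classifier scores each
(query, candidate) sentence pair with a probability of semantic equivalence
(`pair_scores()`). Candidates scoring below `threshold` are eliminated.

**Stage 3, winner selection.** Among survivors the winner maximizes
`w1 * probability + w2 * string_similarity`, where the string similarity is a
normalized Levenshtein ratio between the query *name* and the candidate's
term name (names, not descriptions — edit distance on long free text says
little about variable identity). With `use_prior_knowledge = TRUE` the
comparison set is first expanded by every cohort variable already mapped onto
a retrieved term; if such an alias wins, the known mapping is reversed and
its parent term returned. No survivors means `no_match`.

The elimination threshold applies to the raw classifier probability, and the
w1/w2 blend only ranks the survivors. Blending *before* elimination would let
a high string similarity rescue a pair the classifier rejected, which
contradicts the role of the threshold as a semantic veto.

## Offline backends

The package must train and run with no model downloads, so both learned
components have self-contained implementations behind pluggable contracts;
a transformer encoder or cross-encoder can replace them via
`manual_encoder()` / `manual_pair_classifier()` without touching the rest of
the cascade.

**Encoder.** `ngram_encoder()` hashes the character 3-gram multiset of the
lowercased sentence (padded with `^`/`$` boundary markers so one- and
two-character names still produce grams) into `embedding_dim` buckets and
L2-normalizes the counts. Hashing uses a polynomial rolling hash keyed by the
seed; all arithmetic stays below 2⁵³ so the double-precision modulo is exact
and vectors are bit-reproducible across platforms. Character n-grams are a
good fit for variable names, which vary mainly by case, separators,
truncation and abbreviation.

**Embedder training (retrieval metric).** `train_embedder()` learns a
diagonal re-weighting s of the embedding dimensions by minimizing a
margin-1.0 triplet loss on squared Euclidean distances over
(alias, own term, same-modality other term) triplets, one per mapped
variable, with the negative drawn uniformly under the seed. Projected
full-batch gradient descent (40 epochs, step 0.5, scales clamped at 0) keeps
the fit deterministic; zero epochs return the initial encoder unchanged. A
diagonal metric was chosen over a full linear map because it has d parameters
instead of d², cannot overfit a desk-scale CDM, and directly captures the
useful effect: down-weighting hash buckets dominated by cohort-specific noise
(suffixes, style tokens) and up-weighting discriminative content grams.

**Pair classifier (reranker).** A weighted logistic model on the features
`[1, |a − b|, a ⊙ b]` of the two sentence embeddings — the same shape as a
feed-forward classification head over a pair representation. Training is
full-batch gradient descent from zero weights with backtracking step halving
(default 150 epochs, initial step 8, the step recovering after successful
updates), which guarantees the weighted training loss never exceeds its
initialization value and makes the fit fully deterministic with no RNG. The
per-pair class weights enter the loss directly.

## Training data construction

Positive pairs are generated from the CDM's curated mapping edges. The
default `all_combinations` mode emits every unordered pair from
`{term} ∪ {its aliases}` per term — reading "combinations of mappings" as the
full clique — while `ref_to_variable` mode (one pair per edge) is retained as
a flag because the narrower reading is also defensible.

Negative pairs join two items of the *same modality* belonging to *different
terms*: variables grouped in one modality share naming conventions, so these
are the confusable cases a reranker must learn — most pointedly the
left/right lateralized volume pairs. Negatives are sampled without
replacement, never duplicate a positive pair (as unordered sentence pairs),
and are stratified across modalities proportionally to each modality's
positive count so the hard-negative pressure follows the data. Both items of
a negative may be variables or reference terms; the contract constrains
modality and term identity, not item kind. Requesting more distinct negatives
than exist raises a capacity error that reports the achievable maximum.

Class weights default to 0.1 for negatives and 0.9 for positives, and the
train/test/validation split defaults to fractions 0.80/0.04/0.16 (the test
part deliberately smaller than validation), with sizes `floor(f * n)` and the
remainder assigned to training. Equal positive and negative counts keep the
classes balanced; the weights then shape the loss, not the sampling.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `K` | 5 | candidates retrieved; 5 is a sufficient standard at 10³-term scale, and accuracy typically plateaus between K = 5 and K = 10 |
| `w1`, `w2` | 1.0, 0.0 | weights of classifier probability and string similarity; not forced to sum to 1 — each is validated only to [0, 1] |
| `threshold` | 0.5 | elimination threshold on the classifier probability |
| `use_prior_knowledge` | off | expand candidates with known mappings; helps when the new cohort shares conventions with a mapped cohort, and can hurt otherwise |
| `embedding_dim` | 768 | hash buckets of the n-gram encoder / embedding dimension |
| `seed` | 1 | drives every random choice (negative sampling, splits, synthetic data) |

String similarity is `1 − d/max(|a|,|b|)` after lowercasing: case conventions
are noise in variable naming, max-length normalization bounds the value in
[0, 1], and both strings empty defines similarity 1. Unicode is compared per
code point with no accent folding.

## The synthetic benchmark

`synthetic_spec()` + `generate_reference_terms()` + `generate_cohort_variants()`
build CDMs from a built-in vocabulary of 63 concept phrases spanning
demographics, cognitive scores, clinical chemistry, CSF/plasma biomarkers,
structural imaging volumes, PET composites and genetics, crossed with visit
qualifiers (baseline, month 12/24, change from baseline) for a universe of
~300 terms. A configurable fraction of terms is emitted as left/right pairs
differing by one character — the lateralized hard-negative structure. Each
cohort gets a persistent naming style (case, separator, laterality marker
placement) plus per-term stochastic transforms: initials, truncation, vowel
dropping, synonym/abbreviation swaps, cohort suffixes, dropped or shortened
descriptions. When no name rule fires the variant equals the term name
verbatim, which keeps an identity channel for sanity checks. Vowel dropping
is applied last among the name transforms so that, at probability 1, no
lowercase vowel survives. Name collisions are retried up to 100 times, then
resolved with a deterministic numeric suffix. Unseen evaluation cohorts are
generated the same way under a derived seed, with names guaranteed disjoint
from the training CDM.

By default concepts keep their natural modality (hippocampal volume is MRI);
an explicit modality list is assigned round-robin over term units instead,
with lateralized pairs kept together — splitting a left/right pair across
modalities would remove exactly the hard negatives the design exists to
create.

The default benchmark conditions are 150 reference terms, 4 training cohorts,
2 unseen cohorts (300 evaluation queries) and 30% lateralized terms. At this
scale the whole generate–train–evaluate loop runs in roughly twenty seconds
on one CPU, and the trained cascade clearly outperforms the string-matching
baseline on unseen cohorts across seeds.

**What passing the synthetic benchmark does and does not show.** The
generator emulates the *structure* of multi-cohort naming variation
(abbreviation, styling, laterality, missing descriptions) but not the
distribution of any real cohort: real dictionaries contain typos, multi-word
free text, domain synonymy beyond the built-in list, and variables genuinely
absent from the CDM. Results on the benchmark therefore validate the
machinery — retrieval geometry, classifier training, thresholding, alias
expansion, evaluation accounting — not a clinical-grade accuracy claim. On
real CDMs with a fine-tuned transformer backend, absolute accuracies will
differ.

## Numerical and design notes

- All orderings use radix (C-locale) sorting, so results are identical across
  locales; unordered pairs are canonicalized the same way.
- Combined-score ties break to the lexicographically smaller term identifier
  (then direct candidates before prior-mapping enrichments, then matched
  name). An embedding-distance tie-break was considered and rejected: the
  degenerate configuration `w1 = 0, w2 = 1, threshold = 0, K = |terms|` must
  agree *exactly* with the string-matching baseline, including ties, and the
  baseline has no embedding distance to consult.
- The identity self-benchmark (every reference term fed back as its own
  name and description) is run at threshold 0 with `w = (1, 0)`: it isolates
  retrieval and ranking of an exact self-match, while threshold semantics are
  exercised separately (threshold 0 must match everything; any threshold
  above the maximum observed probability must match nothing).
- `no_match` results count as errors in `top1_accuracy()` — the conservative
  convention for an accuracy over a labeled evaluation set.
- A variable maps to exactly one reference term (many-to-one). The data layer
  stores text verbatim; case folding happens only inside the encoder and the
  fuzzy comparator. A bare `-`/en-dash description is read as absent.
- JSON is the lossless CDM master format (separate term/variable/mapping
  arrays, canonical row order, byte-stable round trips); the long-format CSV
  mirrors the flat data-dictionary world.
- Known limitations: the bundled encoder cannot capture synonymy with zero
  character overlap (that is what transformer backends are for); classifier
  probabilities are not calibrated, so the 0.5 default threshold is a
  convention, not a guarantee; and one variable cannot map to several terms.
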
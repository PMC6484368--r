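---
title: "Indexing narrative data-quality checks with the data element-function model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indexing narrative data-quality checks with the data element-function model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dqindexr)
```

## The problem and the model

Clinical data research networks write their data-quality (DQ) checks as
free narrative text — "Number of persons with at least one drug
occurrence, by drug_concept_id" — in whatever house style the network
uses. Stored this way, checks from different networks cannot be compared,
counted, or indexed against a common terminology.

dqindexr implements a deliberately minimal conceptual model for these
narratives, patterned on entity–attribute–value modeling. Every check is
reduced to exactly two constructs:

* the **data element** — the primary focus of the check ("persons"), and
* the **function** — the qualitative or quantitative measure applied to it
  ("number of").

The check is the entity, the construct kind is the attribute, and the
extracted term is the value. Exactly one data element and one function are
attached per check; this is enforced at every layer (annotation markup,
extraction, indexing), because each check is taken to have one intended
focus. Extracted terms are then mapped into per-network controlled
vocabularies of *domains* (Person, Medication, Count, Missing, ...), which
is what makes cross-network counting and comparison possible. Checks can
additionally carry externally supplied labels from the harmonized DQ
terminology (Conformance / Completeness / Plausibility with their
subcategories); these labels are inputs, never inferred.

Two dialects are packaged. OHDSI-style checks are aggregate, post-ETL
characterizations ("Number of X with at least one Y, by Z"); CESR-style
checks are variable-level intrinsic verifications ("check that X is not
missing", "verify X variable type"). Their vocabularies are kept separate
because the same word can mean different things across networks ("length"
is a time frame in one and a stored variable length in the other).

## Annotation markup

Gold annotations wrap the data element in `[[ ... ]]` and the function in
`{{ ... }}`:

```{r}
p <- parse_annotation(
  "{{ Number of }} [[ persons ]] with at least one drug occurrence, by drug_concept_id"
)
p$text
p$annotation
```

Spans are 0-based half-open character intervals into the de-marked text,
which keeps concatenation and slicing arithmetic unambiguous.
`write_annotation()` is the exact inverse (property-tested under
randomized marker placement). Zero or multiple blocks of either kind are
annotation-guideline violations and raise errors rather than warnings.

## The extractor

The original acquisition work repurposed a pre-existing clinical-trial
eligibility NLP system whose internals are not reproducible from its
description; dqindexr instead implements extraction from first principles
as dictionary NER with context-template backoff, which is sufficient for
the highly structured narrative style of network DQ checks:

* **Term lexicon** — every annotated span's normalized surface form.
  Normalization case-folds and collapses whitespace but preserves
  punctuation (`drug_concept_id` must survive); token-edge punctuation is
  stripped on both sides of a comparison so "occurrence," matches
  "occurrence".
* **Context templates** — the tokens flanking each gold span (window of 2
  on each side by default, `<s>` at text boundaries). Context tokens that
  fall inside the *other* construct's gold span are generalized to a
  one-token wildcard `*`; at extraction time a wildcard must align with
  the other construct's extracted span when that span is known, and a
  template with no concrete anchor token is not applied while the other
  span is unknown. This is what lets a template learned from "Number of
  [[ persons ]] with ..." recover an unseen data element from "Number of
  care sites with ..." without also matching arbitrary junk spans.
* **Modifier stoplist** — adjective modifiers ("distinct", "unique",
  "total", user-extensible) are trimmed from the front of data-element
  template candidates, so "Number of distinct persons" yields "persons",
  not "distinct".
* **Clause truncation** — stratification and temporal clauses ("by
  drug_concept_id", "across all years") are narrative qualifiers the
  two-construct model deliberately does not capture; template candidates
  are truncated at the first clause marker (`by`, `across`). Lexicon
  matches are exempt because vocabulary terms may legitimately contain
  these words ("paid by payer").

Candidate selection is longest match then leftmost, the standard
dictionary-NER tie-break; lexicon candidates take precedence over
template candidates. Extraction is total: a check with no candidate for a
construct yields an `UNKNOWN` record, never an error, because unmapped
material is exactly what a human reviewer needs to see.

Evaluation scores a construct as correct iff the extracted term equals
the gold term under normalization — string equality, not span overlap,
which is the stricter and more reproducible reading of "correctly
identified".

## The iterative annotate-train loop

`iterative_train()` reproduces the bootstrap protocol: draw a random
initial annotation subset, train, evaluate on the *full* training corpus,
and while either construct's proportion correct is below the threshold
(default 90%), add the missed checks' annotations and retrain. The subset
grows strictly every iteration, so the loop always terminates; exhausting
`max_iterations` (default 10) below threshold raises a
`dqindexr_nonconvergence` warning carrying the full per-iteration trace —
never a silent success.

The training-fraction split is exposed with a configurable rounding rule
(`split_corpus(round_mode = "nearest" | "up" | "down")`, nearest with ties
up by default) because published split sizes of real corpora are reported
under more than one convention (a 10% split of 172 checks has been
reported as 18, which nearest-rounding gives as 17).

## Taxonomies and categorization

`ohdsi_taxonomy()` and `cesr_taxonomy()` load the packaged controlled
vocabularies: 49 data-element terms over 12 domains plus 3 function terms
over 3 domains for OHDSI; 21 function terms over 14 domains for CESR. The
full CESR data-element list is proprietary: only per-domain sample terms
and per-domain unique-term cardinalities are public. dqindexr therefore
packages the printed samples and synthesizes the remainder as clearly
marked placeholder terms (`medication_term_17`) up to each published
cardinality — 702 terms over 23 domains (`generate_cesr_lexicon()`). The
placeholders are a synthetic stand-in for vocabulary *size*, not content;
analyses that depend on which real terms exist cannot be run against them.

Matching is case-insensitive by default while unique-term counting is
case-sensitive by default ("race1" and "RACE1" are two terms that map to
one domain); both are configurable. Lookup is total — unknown terms
resolve to the `UNCATEGORIZED` sentinel. An opt-in fallback
(`fallback = TRUE`) implements the most-relevant-domain adjudication
rule: longest shared token suffix (the head noun of these noun phrases)
against the vocabulary, with specific domains preferred over the
unspecified catch-alls (Date, Observations, Numeric Values), so a date
defined in relation to a concrete entity resolves to that entity's
domain. It is off by default because categorization of unseen terms was a
manual, consensus-based step in the reference workflow; a heuristic
should be a deliberate choice.

Cross-network comparison (`dq_domain_overlap()`) collapses only trivial
singular/plural spelling variants. Semantic near-matches — an
insurance-specific domain vs a broader socioeconomic one, calculated age
vs date of birth — are deliberately not overlaps: they are associated but
do not refer to the same meaning.

## The synthetic generator

Both real corpora are unavailable (one partly proprietary), so the
generator is a first-class module, not a test fixture. It emits
gold-annotated checks through per-network narrative templates with three
slots: function phrase, data-element phrase, and an optional distractor
(stratifier clause at `stratifier_rate`, stoplist modifier at
`modifier_rate`). Defaults follow the study conditions: replica specs use
modifier rate 0 and the published per-domain check counts.

The replica specs (`replica_spec("OHDSI")`, 172 checks;
`replica_spec("CESR")`, 3,434 checks) reproduce the published
"count of checks in domain" columns exactly. The joint data-element ×
function domain distribution is only partially published; the replica
YAML files pin the individually quoted cells (e.g. Person–Count 55,
Medication–Variable Type 175, all 49 Sum checks in Socioeconomic Factors,
24 of 29 Trend checks on Date, 18 of 29 Uniqueness checks on MRN) and
fill the remaining mass with a deterministic greedy transport over
alphabetically ordered domains that never touches a pinned cell. Which
cells are published and which are fill is recorded in the YAML comments;
any analysis of unpinned cells reflects the fill rule, not the source
networks. Harmonization labels are attached by deterministic
per-function-domain rules stated in the same files. Term-level assignment
within a domain is round-robin in vocabulary order, and all remaining
randomness (check order, distractor draws) is governed by the spec seed;
generation is byte-identical for a fixed spec + seed.

What the generator does *not* emulate: free-text checks outside the two
templated dialects, multi-construct checks, misspellings, and the
long-tail phrasing variation of real corpora. Extraction results on
generated corpora therefore measure the protocol's internal consistency,
not real-corpus NLP performance — the published real-corpus test figures
(e.g. 76% data elements / 98% functions on held-out aggregate-dialect
checks) are not reproducible without the original narratives and are not
claimed by this package's tests.

## Numerical and design choices

* Percentages in frequency tables are reported both at full precision
  (`pct`) and rounded to whole percent (`pct_label`), matching the usual
  reporting style; rounding can make labels sum slightly off 100.
* Tie-breaks everywhere are deterministic (longest match then leftmost;
  alphabetical ordering of domains in matrices and the greedy fill).
* Degenerate inputs are first-class: empty corpora error early with named
  messages, empty frequency tables are empty tibbles, zero-count
  generator specs warn and emit empty corpora, and `UNKNOWN` /
  `UNCATEGORIZED` sentinels propagate instead of erroring mid-pipeline.
* Problem sizes in the test suite are scaled-down replicas (tens to a few
  hundred checks; the full 3,434-check CESR replica is generated once for
  the marginal-fidelity checks), chosen so the whole suite exercises
  every code path at interactive speeds.
* `scale_spec()` downsizes a replica systematically over the expanded
  check list rather than by per-row largest remainder, because the CESR
  marginals fragment into thousands of single-check term rows where
  largest-remainder rounding would silently drop whole function domains.

## A worked run

```{r, eval = FALSE}
library(dqindexr)

spec <- scale_spec(replica_spec("OHDSI"), 200, modifier_rate = 0.1,
                   seed = 42)
gen <- generate_corpus(spec)

run <- iterative_train(gen$corpus, gen$annotations,
                       initial_subset_size = 20, threshold = 0.90,
                       max_iterations = 10, seed = 1)
tidy(run)       # per-iteration proportions
glance(run)     # one-row summary

model <- run$model
recs <- extract_constructs(model, gen$corpus)
indexed <- index_checks(gen$corpus, recs, ohdsi_taxonomy())

dq_frequency_table(indexed, "data_element")
autoplot(dq_pairing_matrix(indexed))
```

The same workflow is scriptable as staged commands with JSON manifests
(`dq_run_simulate()` through `dq_run_report()`, or the `inst/cli/dqindex.R`
wrapper) for shell use.

## Known limitations

* The two-construct model loses information by design: stratifications,
  temporal constraints and secondary data elements are not captured, only
  deliberately excluded from extracted terms.
* The extractor is lexicon + templates; it will not generalize across
  narrative styles it has never seen annotated, and cross-network
  transfer is intentionally unsupported (models are per-network).
* The synthesized CESR data-element lexicon preserves cardinalities, not
  contents; term-level CESR results are placeholders.
* Unpinned cells of the replica pairing matrices follow the documented
  fill rule and must not be read as published values.
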
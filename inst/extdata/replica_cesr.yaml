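# Replica generator spec for the CESR-dialect corpus (3,434 checks).
# de_marginals / fn_marginals are the published per-domain check counts;
# pinned_pairs are the individually published pairing-matrix cells (the
# five most common pairs plus the concentrated Sum / Trend / Uniqueness
# cells). Remaining joint mass is filled deterministically. The full CESR
# data-element term list is proprietary, so checks draw their terms from
# the cardinality-faithful synthesized lexicon (generate_cesr_lexicon()).
network: CESR
n_checks: 3434
modifier_rate: 0.0
stratifier_rate: 0.0
de_marginals:
  - {domain: Birth, count: 11}
  - {domain: Bone Measurement, count: 42}
  - {domain: Care Site, count: 20}
  - {domain: Condition, count: 85}
  - {domain: Date, count: 24}
  - {domain: Death, count: 24}
  - {domain: Enrollment, count: 30}
  - {domain: Ethnicity, count: 10}
  - {domain: Gender, count: 10}
  - {domain: Internal ID, count: 144}
  - {domain: Lab, count: 121}
  - {domain: Language, count: 36}
  - {domain: Medication, count: 764}
  - {domain: MRN, count: 153}
  - {domain: Observations, count: 184}
  - {domain: Procedure, count: 43}
  - {domain: Provider, count: 146}
  - {domain: Race, count: 97}
  - {domain: Social History, count: 216}
  - {domain: Socioeconomic Factors, count: 464}
  - {domain: Tumor, count: 534}
  - {domain: Visit, count: 190}
  - {domain: Vital, count: 86}
fn_marginals:
  - {domain: Category, count: 243}
  - {domain: Consistency, count: 10}
  - {domain: Count, count: 380}
  - {domain: Cross tab, count: 19}
  - {domain: Distribution, count: 1}
  - {domain: Existence, count: 715}
  - {domain: Link, count: 41}
  - {domain: Missing, count: 722}
  - {domain: Overlap, count: 3}
  - {domain: Sum, count: 49}
  - {domain: Trend, count: 29}
  - {domain: Uniqueness, count: 29}
  - {domain: Variable Length, count: 467}
  - {domain: Variable Type, count: 726}
pinned_pairs:
  - {de_domain: Medication, fn_domain: "Variable Type", count: 175}
  - {de_domain: Medication, fn_domain: Missing, count: 172}
  - {de_domain: Medication, fn_domain: Existence, count: 152}
  - {de_domain: Medication, fn_domain: Count, count: 127}
  - {de_domain: "Socioeconomic Factors", fn_domain: "Variable Type", count: 114}
  - {de_domain: "Socioeconomic Factors", fn_domain: Sum, count: 49}
  - {de_domain: Date, fn_domain: Trend, count: 24}
  - {de_domain: MRN, fn_domain: Uniqueness, count: 18}
# Deterministic per-function-domain harmonization labels, following the
# published pattern (variable-level intrinsic verification): existence and
# linkage checks are Relational Conformance, type/length/category checks
# are Value Conformance, missingness and counts are Atemporal Completeness,
# trend is Temporal Plausibility, uniqueness is Uniqueness Plausibility.
harmonization_rules:
  - {fn_domain: Category, categories: [Conformance-Value]}
  - {fn_domain: Consistency, categories: [Plausibility-Atemporal]}
  - {fn_domain: Count, categories: [Completeness-Atemporal]}
  - {fn_domain: "Cross tab", categories: [Plausibility-Atemporal]}
  - {fn_domain: Distribution, categories: [Plausibility-Atemporal]}
  - {fn_domain: Existence, categories: [Conformance-Relational]}
  - {fn_domain: Link, categories: [Conformance-Relational]}
  - {fn_domain: Missing, categories: [Completeness-Atemporal]}
  - {fn_domain: Overlap, categories: [Plausibility-Atemporal]}
  - {fn_domain: Sum, categories: [Conformance-Calculation]}
  - {fn_domain: Trend, categories: [Plausibility-Temporal]}
  - {fn_domain: Uniqueness, categories: [Plausibility-Uniqueness]}
  - {fn_domain: "Variable Length", categories: [Conformance-Value]}
  - {fn_domain: "Variable Type", categories: [Conformance-Value]}
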
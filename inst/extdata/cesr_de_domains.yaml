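# Per-domain metadata for the CESR data-element vocabulary. The full term
# list is proprietary; only sample terms are packaged
# (cesr_de_sample_vocabulary.csv). `n_unique_terms` is the published
# per-domain cardinality (case-sensitive unique term count, 702 in total);
# `n_checks` is the published count of checks whose data element falls in
# the domain (3434 in total). generate_cesr_lexicon() synthesizes clearly
# marked placeholder terms up to each cardinality.
domains:
  - {domain: Birth, n_unique_terms: 4, n_checks: 11, definition: DEs related to birth-related variables}
  - {domain: Bone Measurement, n_unique_terms: 10, n_checks: 42, definition: DEs related to bone measurement variables}
  - {domain: Care Site, n_unique_terms: 2, n_checks: 20, definition: DEs related to place of care specific variables}
  - {domain: Condition, n_unique_terms: 17, n_checks: 85, definition: DEs related primarily to condition-specific variables}
  - {domain: Date, n_unique_terms: 2, n_checks: 24, definition: DEs related to unspecified date variables}
  - {domain: Death, n_unique_terms: 6, n_checks: 24, definition: DEs related to death-specific variables}
  - {domain: Enrollment, n_unique_terms: 11, n_checks: 30, definition: DEs related to enrollment-specific variables}
  - {domain: Ethnicity, n_unique_terms: 2, n_checks: 10, definition: DEs related to ethnicity-specific variables}
  - {domain: Gender, n_unique_terms: 2, n_checks: 10, definition: DEs related to gender-specific variables}
  - {domain: Internal ID, n_unique_terms: 53, n_checks: 144, definition: DEs defined by internally utilized constructions}
  - {domain: Lab, n_unique_terms: 26, n_checks: 121, definition: DEs related to lab-specific variables}
  - {domain: Language, n_unique_terms: 8, n_checks: 36, definition: DEs related to speaking language variables}
  - {domain: Medication, n_unique_terms: 120, n_checks: 764, definition: DEs related to medication-specific variables}
  - {domain: MRN, n_unique_terms: 12, n_checks: 153, definition: DEs related to medical record numbers}
  - {domain: Observations, n_unique_terms: 43, n_checks: 184, definition: DEs related to ambiguous variables}
  - {domain: Procedure, n_unique_terms: 8, n_checks: 43, definition: DEs related to procedure-specific variables}
  - {domain: Provider, n_unique_terms: 26, n_checks: 146, definition: DEs related to provider-specific variables}
  - {domain: Race, n_unique_terms: 24, n_checks: 97, definition: DEs related to race-specific variables}
  - {domain: Social History, n_unique_terms: 53, n_checks: 216, definition: DEs related to social history variables}
  - {domain: Socioeconomic Factors, n_unique_terms: 117, n_checks: 464, definition: DEs related to socioeconomic variables}
  - {domain: Tumor, n_unique_terms: 107, n_checks: 534, definition: DEs related to cancer-specific variables}
  - {domain: Visit, n_unique_terms: 29, n_checks: 190, definition: DEs related to visit-specific variables}
  - {domain: Vital, n_unique_terms: 20, n_checks: 86, definition: DEs related to vital-specific variables}
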
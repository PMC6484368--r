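# Replica generator spec for the OHDSI-dialect corpus (172 checks).
# de_marginals / fn_marginals are the published per-domain check counts.
# pinned_pairs are the individually published pairing-matrix cells; the
# remaining joint mass is filled by a deterministic greedy transport over
# alphabetically ordered domains (see build_pairing_cells()).
network: OHDSI
n_checks: 172
modifier_rate: 0.0
stratifier_rate: 1.0
de_marginals:
  - {domain: Age, count: 10}
  - {domain: Care Site, count: 3}
  - {domain: Condition, count: 15}
  - {domain: Death, count: 9}
  - {domain: Insurance, count: 23}
  - {domain: Medication, count: 20}
  - {domain: Numeric Values, count: 1}
  - {domain: Observations, count: 16}
  - {domain: Person, count: 55}
  - {domain: Procedure, count: 8}
  - {domain: Provider, count: 3}
  - {domain: Visit, count: 9}
fn_marginals:
  - {domain: Count, count: 128}
  - {domain: Distribution, count: 39}
  - {domain: Time Length, count: 5}
pinned_pairs:
  - {de_domain: Person, fn_domain: Count, count: 55}
  - {de_domain: Insurance, fn_domain: Distribution, count: 17}
  - {de_domain: Medication, fn_domain: Count, count: 16}
  - {de_domain: Condition, fn_domain: Count, count: 14}
  - {de_domain: Observations, fn_domain: Count, count: 13}
# Harmonization labels follow the published per-function-domain pattern:
# Time Length checks are Calculation Conformance, Distribution checks are
# Atemporal Plausibility, Count checks alternate between Atemporal and
# Temporal Plausibility (deterministic by check order).
harmonization_rules:
  - {fn_domain: "Time Length", categories: [Conformance-Calculation]}
  - {fn_domain: Distribution, categories: [Plausibility-Atemporal]}
  - {fn_domain: Count, categories: [Plausibility-Atemporal, Plausibility-Temporal]}
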
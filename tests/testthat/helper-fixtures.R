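# Fixtures are built in code. The cache avoids regenerating the large
# replica corpora across test files.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_cache)) {
    assign(key, force(expr), envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

replica_gen <- function(network, seed = 7L) {
  cached(paste0("replica_", network, "_", seed),
         generate_corpus(replica_spec(network, seed = seed)))
}

# A tiny hand-annotated OHDSI-style corpus (aggregate characterization
# phrasing) used by extractor unit tests.
tiny_annotated <- function() {
  dq_corpus(
    c("{{ Number of }} [[ persons ]] with at least one drug occurrence, by drug_concept_id",
      "{{ Number of }} [[ visit records ]] with at least one condition occurrence, by year",
      "{{ Distribution of }} [[ age ]] by site",
      "{{ Length of }} [[ length of stay ]] by year"),
    network = "OHDSI"
  )
}

# k mutually patternless checks: every token is unique to its check, so no
# lexicon entry or context template learned from one check can apply to
# another.
patternless_annotated <- function(k) {
  dq_corpus(
    sprintf("alpha%1$d {{ beta%1$d }} gamma%1$d [[ delta%1$d ]] epsilon%1$d",
            seq_len(k)),
    network = "OTHER"
  )
}
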
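# Tokenization and term normalization shared by the extractor, the
# taxonomies and the evaluator.
#
# Check narratives are short and regular, so tokens are whitespace-delimited
# with punctuation kept attached; each token additionally carries a "match
# form" with edge punctuation stripped and case folded, so that
# "occurrence," matches the vocabulary token "occurrence" while interior
# punctuation ("drug_concept_id", "out-of-pocket") is preserved.

# Collapse whitespace, trim, case-fold. Punctuation is preserved: terms like
# "drug_concept_id" are significant.
normalize_term <- function(x) {
  tolower(trimws(gsub("[[:space:]]+", " ", x)))
}

strip_edge_punct <- function(tok) {
  sub("[,.;:!?\"']+$", "", sub("^[(\\[\"']+", "", tok))
}

# Match key of a (possibly multi-word) term: per-token edge punctuation
# stripped, case folded, single-space joined.
term_key <- function(term) {
  vapply(term, function(t) {
    toks <- strsplit(trimws(t), "[[:space:]]+")[[1]]
    paste(strip_edge_punct(tolower(toks)), collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

# Tokenize one narrative. Returns a tibble with the surface form, 0-based
# half-open character offsets, and the match form.
tokenize_text <- function(text) {
  if (trimws(text) == "") {
    return(tibble(surface = character(), start = integer(), end = integer(),
                  match = character()))
  }
  m <- gregexpr("[^[:space:]]+", text)[[1]]
  tibble(
    surface = regmatches(text, list(m))[[1]],
    start = as.integer(m) - 1L,
    end = as.integer(m) - 1L + attr(m, "match.length")
  ) |>
    mutate(match = strip_edge_punct(tolower(.data$surface)))
}

# Surface string of tokens i..j with outer edge punctuation removed (the
# punctuation belongs to the sentence, not the term).
token_span_surface <- function(text, tokens, i, j) {
  raw <- substr(text, tokens$start[i] + 1L, tokens$end[j])
  sub("[,.;:!?\"']+$", "", sub("^[(\\[\"']+", "", raw))
}
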
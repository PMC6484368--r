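# Controlled-vocabulary categorization of extracted terms into domains.
#
# Each network carries its own taxonomy: a set of (term, construct kind,
# domain) entries plus one-line domain definitions. Matching is
# case-insensitive by default while *uniqueness counting* is case-sensitive
# by default ("race1" and "RACE1" are two terms but match the same domain);
# both policies are configurable.

#' Build a taxonomy from a vocabulary table
#'
#' @param entries Tibble with columns `network`, `construct_kind`, `term`,
#'   `domain`, `definition` (one row per term).
#' @param network Dialect tag; defaults to the one in `entries`.
#' @param case_sensitive_match Should term lookup respect case? Default
#'   `FALSE`.
#' @return An object of class `dq_taxonomy`.
#' @export
dq_taxonomy <- function(entries, network = NULL,
                        case_sensitive_match = FALSE) {
  required <- c("construct_kind", "term", "domain", "definition")
  missing <- setdiff(required, names(entries))
  if (length(missing)) {
    abort(sprintf("vocabulary lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  entries <- as_tibble(entries)
  bad_kind <- setdiff(unique(entries$construct_kind), construct_kinds())
  if (length(bad_kind)) {
    abort(sprintf("unknown construct_kind value(s): %s",
                  paste(bad_kind, collapse = ", ")))
  }
  network <- network %||% unique(entries$network)[1] %||% "OTHER"
  entries <- mutate(entries, key = term_key(.data$term))
  conflicts <- entries |>
    distinct(.data$key, .data$construct_kind, .data$domain) |>
    count(.data$key, .data$construct_kind) |>
    filter(.data$n > 1)
  if (nrow(conflicts) > 0) {
    rows <- entries |>
      filter(.data$key %in% conflicts$key) |>
      mutate(lab = sprintf("'%s' (%s) -> %s", .data$term,
                           .data$construct_kind, .data$domain))
    abort(sprintf("vocabulary conflict: term(s) mapped to multiple domains: %s",
                  paste(rows$lab, collapse = "; ")))
  }
  definitions <- distinct(entries, .data$domain, .data$definition)
  if (anyDuplicated(definitions$domain)) {
    definitions <- definitions |> group_by(.data$domain) |> slice(1) |> ungroup()
  }
  if (any(is.na(definitions$definition) | definitions$definition == "")) {
    abort("every domain must carry a definition")
  }
  structure(
    list(network = network, entries = entries, definitions = definitions,
         case_sensitive_match = case_sensitive_match),
    class = "dq_taxonomy"
  )
}

#' @export
print.dq_taxonomy <- function(x, ...) {
  cat(sprintf("<dq_taxonomy> %s: %d terms, %d domains\n", x$network,
              nrow(distinct(x$entries, .data$term, .data$construct_kind)),
              length(unique(x$entries$domain))))
  invisible(x)
}

#' Load a taxonomy from a vocabulary CSV file
#'
#' Expected columns: `network`, `construct_kind`, `term`, `domain`,
#' `definition`, one row per term (UTF-8). A term mapped to two different
#' domains within one construct kind is a vocabulary conflict and is
#' rejected with an error naming the offending rows.
#'
#' @param path Path to the CSV file (or several, combined).
#' @param ... Passed to [dq_taxonomy()].
#' @return A `dq_taxonomy`.
#' @export
load_taxonomy <- function(path, ...) {
  entries <- purrr::list_rbind(purrr::map(path, function(p) {
    if (!file.exists(p)) abort(sprintf("vocabulary file not found: %s", p))
    readr::read_csv(p, col_types = readr::cols(.default = "c"),
                    na = character())
  }))
  dq_taxonomy(entries, ...)
}

#' Packaged OHDSI taxonomy (data elements + functions)
#'
#' The transcribed OHDSI controlled vocabulary: 49 data-element terms over
#' 12 domains and 3 function terms over 3 domains (Count, Distribution,
#' Time Length).
#'
#' @return A `dq_taxonomy`.
#' @export
ohdsi_taxonomy <- function() {
  load_taxonomy(system.file("extdata", "ohdsi_vocabulary.csv",
                            package = "dqindexr"),
                network = "OHDSI")
}

#' Packaged CESR taxonomy
#'
#' The CESR function vocabulary is packaged in full (21 terms over 14
#' domains). The data-element vocabulary is proprietary and only published
#' as per-domain sample terms plus per-domain cardinalities; by default the
#' sample terms are loaded, and a cardinality-faithful synthesized lexicon
#' (see [generate_cesr_lexicon()]) can be supplied instead.
#'
#' @param de_lexicon Optional data-element vocabulary tibble replacing the
#'   packaged sample terms.
#' @return A `dq_taxonomy`.
#' @export
cesr_taxonomy <- function(de_lexicon = NULL) {
  fn <- readr::read_csv(
    system.file("extdata", "cesr_fn_vocabulary.csv", package = "dqindexr"),
    col_types = readr::cols(.default = "c"), na = character()
  )
  de <- de_lexicon %||% readr::read_csv(
    system.file("extdata", "cesr_de_sample_vocabulary.csv",
                package = "dqindexr"),
    col_types = readr::cols(.default = "c"), na = character()
  )
  dq_taxonomy(bind_rows(de, fn), network = "CESR")
}

#' Published per-domain metadata for the CESR data-element vocabulary
#'
#' @return Tibble with columns `domain`, `n_unique_terms`, `n_checks`,
#'   `definition` (23 domains; cardinalities sum to 702, check counts to
#'   3434).
#' @export
cesr_de_domains <- function() {
  raw <- yaml::read_yaml(system.file("extdata", "cesr_de_domains.yaml",
                                     package = "dqindexr"))
  purrr::list_rbind(purrr::map(raw$domains, as_tibble)) |>
    mutate(n_unique_terms = as.integer(.data$n_unique_terms),
           n_checks = as.integer(.data$n_checks))
}

# Catch-all domains whose definitions are anchored to no named entity;
# specific domains win over these in fallback matching.
catch_all_domains <- function() c("Date", "Observations", "Numeric Values")

strip_plural <- function(tok) sub("(?<=[a-z])s$", "", tok, perl = TRUE)

fallback_domain <- function(tax, key, kind) {
  # most-relevant-domain rule: longest shared token suffix (head noun)
  # against the vocabulary, specific domains preferred over catch-alls
  qtoks <- strip_plural(strsplit(key, " ", fixed = TRUE)[[1]])
  ent <- tax$entries[tax$entries$construct_kind == kind, ]
  if (length(qtoks) == 0 || nrow(ent) == 0) return(uncategorized())
  score <- vapply(ent$key, function(k) {
    vtoks <- strip_plural(strsplit(k, " ", fixed = TRUE)[[1]])
    n <- 0L
    while (n < min(length(qtoks), length(vtoks)) &&
           qtoks[length(qtoks) - n] == vtoks[length(vtoks) - n]) {
      n <- n + 1L
    }
    n
  }, integer(1))
  if (max(score) == 0L) return(uncategorized())
  domains <- sort(unique(ent$domain[score == max(score)]))
  specific <- setdiff(domains, catch_all_domains())
  if (length(specific)) specific[1] else domains[1]
}

#' Map extracted terms to taxonomy domains
#'
#' Exact normalized-term lookup against the taxonomy; lookup is total —
#' every input yields a domain name or the [uncategorized()] sentinel,
#' never an error. With `fallback = TRUE` (off by default, because manual
#' adjudication is the reference behaviour) unmatched terms are resolved by
#' the most-relevant-domain rule: the vocabulary term sharing the longest
#' token suffix (head noun) wins, and among tied domains a specific domain
#' is preferred over an unspecified catch-all (Date, Observations, Numeric
#' Values) — a term naming a date in relation to a concrete entity resolves
#' to that entity's domain rather than to the unspecified Date domain.
#'
#' @param tax A `dq_taxonomy`.
#' @param term Character vector of extracted terms ("" for UNKNOWN
#'   records).
#' @param kind Construct kind(s), recycled along `term`.
#' @param fallback Enable the most-relevant-domain heuristic.
#' @return Character vector of domain names / `"UNCATEGORIZED"`.
#' @examples
#' tax <- ohdsi_taxonomy()
#' categorize_term(tax, "persons", "data_element")
#' @export
categorize_term <- function(tax, term, kind, fallback = FALSE) {
  kind <- rep_len(match.arg(kind, construct_kinds(), several.ok = TRUE),
                  length(term))
  keys <- term_key(term)
  if (tax$case_sensitive_match) {
    entry_keys <- vapply(strsplit(trimws(tax$entries$term), "[[:space:]]+"),
                         function(t) paste(strip_edge_punct(t), collapse = " "),
                         character(1))
    keys <- vapply(strsplit(trimws(term), "[[:space:]]+"),
                   function(t) paste(strip_edge_punct(t), collapse = " "),
                   character(1))
  } else {
    entry_keys <- tax$entries$key
  }
  vapply(seq_along(term), function(i) {
    if (is.na(term[i]) || trimws(term[i]) == "") return(uncategorized())
    hit <- which(entry_keys == keys[i] &
                   tax$entries$construct_kind == kind[i])
    if (length(hit)) return(tax$entries$domain[hit[1]])
    if (fallback) fallback_domain(tax, term_key(term[i]), kind[i])
    else uncategorized()
  }, character(1))
}

#' Count unique vocabulary terms per domain
#'
#' Distinct term strings per domain under the stated case policy
#' (case-sensitive by default, so "race1" and "RACE1" are two terms).
#'
#' @param tax A `dq_taxonomy`.
#' @param kind Construct kind to count.
#' @param case_sensitive Case policy for distinctness (default `TRUE`).
#' @return Tibble `domain`, `n_terms` plus a `total` attribute; sorted by
#'   descending count.
#' @export
count_unique_terms <- function(tax, kind, case_sensitive = TRUE) {
  kind <- match.arg(kind, construct_kinds())
  ent <- tax$entries |>
    filter(.data$construct_kind == kind) |>
    mutate(u = if (case_sensitive) .data$term else tolower(.data$term)) |>
    distinct(.data$domain, .data$u)
  out <- ent |> count(.data$domain, name = "n_terms") |>
    arrange(desc(.data$n_terms), .data$domain)
  attr(out, "total") <- sum(out$n_terms)
  out
}

#' Categorize a corpus's extraction records into indexed checks
#'
#' Joins the corpus, its extraction records and the taxonomy into the
#' indexed-check table that all analyses consume. Records with the
#' `UNKNOWN` flag index as [uncategorized()].
#'
#' @param corpus Corpus tibble.
#' @param extractions Extraction-record tibble (two rows per check, see
#'   [extract_constructs()]).
#' @param tax The network's `dq_taxonomy`.
#' @param fallback Passed to [categorize_term()].
#' @return Tibble of indexed checks (one row per check).
#' @export
index_checks <- function(corpus, extractions, tax, fallback = FALSE) {
  wide <- extractions |>
    select("check_id", "kind", "term") |>
    tidyr::pivot_wider(names_from = "kind", values_from = "term")
  out <- left_join(corpus, wide, by = "check_id") |>
    rename(de_term = "data_element", fn_term = "function")
  if (any(is.na(out$de_term)) || any(is.na(out$fn_term))) {
    abort("every check needs one data_element and one function record")
  }
  out |>
    mutate(
      de_domain = categorize_term(tax, .data$de_term, "data_element", fallback),
      fn_domain = categorize_term(tax, .data$fn_term, "function", fallback)
    ) |>
    select(dplyr::all_of(indexed_check_columns()))
}
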
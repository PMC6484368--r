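# Domain types of the data element-function model.
#
# Every narrative data-quality (DQ) check is modelled as an
# entity-attribute-value triple: the check is the entity, the construct kind
# (data element or function) is the attribute, and the extracted term is the
# value. Collections are plain tibbles so the whole workflow composes with
# dplyr; constructors validate the invariants once, at the boundary.

#' Construct kinds of the data element-function model
#'
#' A DQ check has exactly two constructs: the *data element* (the primary
#' focus of the check, e.g. "persons") and the *function* (the qualitative or
#' quantitative measure applied to it, e.g. "number of").
#'
#' @return Character vector `c("data_element", "function")`.
#' @export
construct_kinds <- function() c("data_element", "function")

#' Sentinel domain for terms absent from a taxonomy
#'
#' Terms that cannot be mapped to any domain of the network's controlled
#' vocabulary are surfaced with this sentinel rather than dropped or errored,
#' so that unmapped terms remain visible for manual review.
#'
#' @return The string `"UNCATEGORIZED"`.
#' @export
uncategorized <- function() "UNCATEGORIZED"

#' Kahn harmonization framework subcategory labels
#'
#' The harmonized DQ assessment terminology has three primary categories with
#' subcategories: Conformance (Value, Relational, Calculation), Completeness
#' (Atemporal, Temporal) and Plausibility (Atemporal, Temporal, Uniqueness).
#' Harmonization labels are always external inputs attached to checks; they
#' are never inferred by this package.
#'
#' @return Character vector of the eight subcategory labels.
#' @export
harmonization_categories <- function() {
  c(
    "Conformance-Value", "Conformance-Relational", "Conformance-Calculation",
    "Completeness-Atemporal", "Completeness-Temporal",
    "Plausibility-Atemporal", "Plausibility-Temporal",
    "Plausibility-Uniqueness"
  )
}

dq_networks <- function() c("OHDSI", "CESR", "OTHER")

#' Build a DQ-check corpus tibble
#'
#' Validates and normalizes a collection of narrative checks into the corpus
#' format used throughout the package: one row per check with a unique
#' `check_id`, the narrative `text` (trimmed of leading/trailing whitespace,
#' interior whitespace preserved), a `network` dialect tag and an optional
#' Kahn `harmonization` label.
#'
#' @param text Character vector of check narratives.
#' @param network Dialect tag: `"OHDSI"`, `"CESR"` or `"OTHER"` (recycled).
#' @param check_id Optional identifiers; defaults to `chk_<row>` in row order.
#' @param harmonization Optional Kahn subcategory labels (see
#'   [harmonization_categories()]); `NA` means unlabeled.
#' @return A tibble with columns `check_id`, `text`, `network`,
#'   `harmonization` and class `dq_corpus`.
#' @examples
#' dq_corpus("Number of persons with at least one drug occurrence", "OHDSI")
#' @export
dq_corpus <- function(text, network = "OTHER", check_id = NULL,
                      harmonization = NULL) {
  text <- trimws(as.character(text))
  if (any(is.na(text) | text == "")) {
    abort("every check narrative must be non-empty after trimming")
  }
  network <- match.arg(network, dq_networks(), several.ok = TRUE)
  if (is.null(check_id)) {
    check_id <- sprintf("chk_%d", seq_along(text))
  }
  check_id <- as.character(check_id)
  if (anyDuplicated(check_id)) {
    abort("check_id values must be unique within a corpus")
  }
  if (is.null(harmonization)) {
    harmonization <- rep(NA_character_, length(text))
  }
  harmonization <- as.character(harmonization)
  bad <- !is.na(harmonization) & !harmonization %in% harmonization_categories()
  if (any(bad)) {
    abort(sprintf(
      "unknown harmonization label(s): %s",
      paste(unique(harmonization[bad]), collapse = ", ")
    ))
  }
  out <- tibble(
    check_id = check_id, text = text,
    network = rep_len(network, length(text)),
    harmonization = rep_len(harmonization, length(text))
  )
  class(out) <- c("dq_corpus", class(out))
  out
}

#' Build an extraction record
#'
#' The EAV "value": one extracted term for one construct of one check. The
#' term is empty exactly when extraction failed (`matched = FALSE`), in which
#' case the record carries the `UNKNOWN` confidence flag.
#'
#' @param check_id Check identifier the record refers to.
#' @param kind Construct kind, `"data_element"` or `"function"`.
#' @param term Extracted surface string; `""` or `NA` mark a failed
#'   extraction.
#' @return One-row tibble with columns `check_id`, `kind`, `term`,
#'   `confidence_flag`.
#' @export
extraction_record <- function(check_id, kind, term) {
  kind <- match.arg(kind, construct_kinds())
  term <- as.character(term %||% "")
  if (is.na(term)) term <- ""
  tibble(
    check_id = as.character(check_id), kind = kind, term = term,
    confidence_flag = ifelse(term == "", "UNKNOWN", "MATCHED")
  )
}

#' Assemble a fully categorized (indexed) check
#'
#' Joins one check with its two extraction records and their assigned
#' domains into the unit of all downstream analyses. Kinds and check ids are
#' cross-checked so no code path can attach two data elements or two
#' functions to one check.
#'
#' @param check One-row corpus tibble (see [dq_corpus()]).
#' @param de,fn Extraction records of kind `"data_element"` and `"function"`
#'   referencing `check$check_id`.
#' @param de_domain,fn_domain Domain names from the network taxonomy, or the
#'   [uncategorized()] sentinel.
#' @return One-row tibble with columns `check_id`, `network`, `de_term`,
#'   `de_domain`, `fn_term`, `fn_domain`, `harmonization`.
#' @export
make_indexed_check <- function(check, de, fn, de_domain, fn_domain) {
  stopifnot(nrow(check) == 1, nrow(de) == 1, nrow(fn) == 1)
  if (de$kind != "data_element" || fn$kind != "function") {
    abort("construct kind mismatch: `de` must be a data_element record and `fn` a function record")
  }
  if (de$check_id != check$check_id || fn$check_id != check$check_id) {
    abort("extraction records must reference the same check_id as `check`")
  }
  if (de$confidence_flag == "UNKNOWN" && de_domain != uncategorized()) {
    abort("an UNKNOWN data-element record can only map to UNCATEGORIZED")
  }
  if (fn$confidence_flag == "UNKNOWN" && fn_domain != uncategorized()) {
    abort("an UNKNOWN function record can only map to UNCATEGORIZED")
  }
  tibble(
    check_id = check$check_id, network = check$network,
    de_term = de$term, de_domain = as.character(de_domain),
    fn_term = fn$term, fn_domain = as.character(fn_domain),
    harmonization = check$harmonization
  )
}

indexed_check_columns <- function() {
  c("check_id", "network", "de_term", "de_domain", "fn_term", "fn_domain",
    "harmonization")
}

#' Write indexed checks to CSV
#'
#' Flat UTF-8 CSV with the canonical column order; the inverse of
#' [read_indexed_checks()].
#'
#' @param checks Tibble of indexed checks.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_indexed_checks <- function(checks, path) {
  stopifnot(all(indexed_check_columns() %in% names(checks)))
  readr::write_csv(checks[indexed_check_columns()], path, na = "")
  invisible(path)
}

#' Read indexed checks from CSV
#'
#' @param path File written by [write_indexed_checks()].
#' @return Tibble of indexed checks.
#' @export
read_indexed_checks <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = character())
  missing <- setdiff(indexed_check_columns(), names(out))
  if (length(missing)) {
    abort(sprintf("indexed-check file lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  out$harmonization[out$harmonization == ""] <- NA_character_
  out[indexed_check_columns()]
}
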
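# Reading and writing check corpora and span-markup annotations.
#
# Corpora arrive one check per row in CSV or XLSX; annotated variants carry
# the check text with the data element wrapped in `[[ ... ]]` and the
# function in `{{ ... }}`. Spans are 0-based half-open character intervals
# into the de-marked (plain) text.

#' Read a DQ-check corpus from CSV or XLSX
#'
#' One check per non-empty row. Identifiers come from an id column when
#' present, otherwise they are assigned sequentially in row order (1-based).
#' Narrative text is trimmed of leading/trailing whitespace; interior
#' whitespace is preserved so annotation spans remain stable.
#'
#' @param path Path to the corpus file.
#' @param network Dialect tag for every check in the file.
#' @param format `"csv"` (UTF-8) or `"xlsx"` (first worksheet only); guessed
#'   from the file extension by default.
#' @param text_col Name of the column holding the check narrative.
#' @param id_col,harmonization_col Optional column names for identifiers and
#'   Kahn harmonization labels.
#' @return A corpus tibble (see [dq_corpus()]).
#' @export
read_corpus <- function(path, network = "OTHER", format = NULL,
                        text_col = "check_text", id_col = "check_id",
                        harmonization_col = "harmonization") {
  if (!file.exists(path)) abort(sprintf("corpus file not found: %s", path))
  format <- format %||%
    (if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "xlsx" else "csv")
  format <- match.arg(format, c("csv", "xlsx"))
  raw <- switch(format,
    csv = readr::read_csv(path, col_types = readr::cols(.default = "c"),
                          na = character(), locale = readr::locale(encoding = "UTF-8")),
    xlsx = readxl::read_excel(path, sheet = 1, col_types = "text")
  )
  if (!text_col %in% names(raw)) {
    abort(sprintf("corpus file %s has no narrative column '%s' (columns: %s)",
                  path, text_col, paste(names(raw), collapse = ", ")))
  }
  raw <- raw[!is.na(raw[[text_col]]) & trimws(raw[[text_col]]) != "", ]
  if (nrow(raw) == 0) abort(sprintf("corpus file %s contains no checks", path))
  ids <- if (id_col %in% names(raw)) raw[[id_col]] else seq_len(nrow(raw))
  harm <- if (harmonization_col %in% names(raw)) {
    h <- as.character(raw[[harmonization_col]])
    h[!is.na(h) & h == ""] <- NA_character_
    h
  } else {
    NULL
  }
  dq_corpus(raw[[text_col]], network = network, check_id = ids,
            harmonization = harm)
}

#' Write a corpus (or annotated corpus) to CSV
#'
#' @param corpus Corpus tibble; an extra `annotated_text` column, if present,
#'   is written as the `check_text` so the file round-trips through
#'   [read_corpus()] + [parse_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  text <- if ("annotated_text" %in% names(corpus)) {
    corpus$annotated_text
  } else {
    corpus$text
  }
  readr::write_csv(
    tibble(check_id = corpus$check_id, check_text = text,
           network = corpus$network, harmonization = corpus$harmonization),
    path, na = ""
  )
  invisible(path)
}

# Locate a `[[ ... ]]` or `{{ ... }}` block. Returns integer positions
# (1-based, inclusive) of the whole block and of the inner term, with the
# optional single padding space inside each marker stripped.
locate_block <- function(text, open, close, label) {
  op <- gregexpr(open, text, fixed = TRUE)[[1]]
  cl <- gregexpr(close, text, fixed = TRUE)[[1]]
  n_open <- sum(op > 0)
  n_close <- sum(cl > 0)
  if (n_open != 1 || n_close != 1) {
    abort(sprintf(
      "annotation-guideline violation: expected exactly one %s block, found %d opener(s)/%d closer(s) in: %s",
      label, n_open, n_close, text
    ))
  }
  if (cl[1] <= op[1]) {
    abort(sprintf("malformed %s block (closer before opener) in: %s", label, text))
  }
  inner <- substr(text, op[1] + 2L, cl[1] - 1L)
  pad_l <- grepl("^ ", inner)
  pad_r <- grepl(" $", inner) && nchar(inner) > 1L
  term <- substr(inner, 1L + pad_l, nchar(inner) - pad_r)
  if (trimws(term) == "") {
    abort(sprintf("empty %s block in: %s", label, text))
  }
  list(
    block_start = op[1], block_end = cl[1] + 1L,
    term = term, n_pad = pad_l + pad_r
  )
}

#' Parse one annotated check into plain text plus spans
#'
#' The markup wraps the data element in `[[ ... ]]` and the function in
#' `{{ ... }}`; exactly one block of each kind must be present and the blocks
#' must not nest or overlap. Markers (and their optional single interior
#' padding spaces) are removed; the inner terms are preserved verbatim.
#'
#' @param annotated_text The marked-up check narrative.
#' @return A list with `text` (the plain narrative) and `annotation`, a
#'   one-row tibble of 0-based half-open spans (`de_start`, `de_end`,
#'   `fn_start`, `fn_end`) indexing into `text`.
#' @examples
#' parse_annotation(
#'   "{{ Number of }} [[ persons ]] with at least one drug occurrence"
#' )
#' @export
parse_annotation <- function(annotated_text) {
  stopifnot(is.character(annotated_text), length(annotated_text) == 1)
  de <- locate_block(annotated_text, "[[", "]]", "data-element")
  fn <- locate_block(annotated_text, "{{", "}}", "function")
  if (!(de$block_end < fn$block_start || fn$block_end < de$block_start)) {
    abort("annotation blocks overlap or nest")
  }
  first <- if (de$block_start < fn$block_start) de else fn
  second <- if (de$block_start < fn$block_start) fn else de
  pre <- substr(annotated_text, 1L, first$block_start - 1L)
  mid <- substr(annotated_text, first$block_end + 1L, second$block_start - 1L)
  post <- substr(annotated_text, second$block_end + 1L, nchar(annotated_text))
  plain <- paste0(pre, first$term, mid, second$term, post)
  # 0-based half-open spans into `plain`
  s1 <- nchar(pre)
  e1 <- s1 + nchar(first$term)
  s2 <- e1 + nchar(mid)
  e2 <- s2 + nchar(second$term)
  if (de$block_start < fn$block_start) {
    ann <- tibble(de_start = s1, de_end = e1, fn_start = s2, fn_end = e2)
  } else {
    ann <- tibble(de_start = s2, de_end = e2, fn_start = s1, fn_end = e1)
  }
  list(text = plain, annotation = ann)
}

span_text <- function(text, start, end) substr(text, start + 1L, end)

check_span <- function(text, start, end, label) {
  if (is.na(start) || is.na(end) || start < 0 || end <= start ||
      end > nchar(text)) {
    abort(sprintf("%s span [%s, %s) is invalid for text of %d characters",
                  label, start, end, nchar(text)))
  }
}

#' Render plain text plus spans back into annotation markup
#'
#' Inverse of [parse_annotation()]: wraps the data-element span in
#' `[[ ... ]]` and the function span in `{{ ... }}`, with single interior
#' padding spaces.
#'
#' @param text Plain check narrative.
#' @param annotation One-row tibble with `de_start`, `de_end`, `fn_start`,
#'   `fn_end` (0-based half-open).
#' @return The marked-up string.
#' @export
write_annotation <- function(text, annotation) {
  a <- annotation
  check_span(text, a$de_start, a$de_end, "data-element")
  check_span(text, a$fn_start, a$fn_end, "function")
  if (a$de_start < a$fn_end && a$fn_start < a$de_end) {
    abort("data-element and function spans overlap")
  }
  spans <- tibble(
    start = c(a$de_start, a$fn_start), end = c(a$de_end, a$fn_end),
    open = c("[[ ", "{{ "), close = c(" ]]", " }}")
  ) |> arrange(.data$start)
  paste0(
    substr(text, 1L, spans$start[1]),
    spans$open[1], span_text(text, spans$start[1], spans$end[1]), spans$close[1],
    substr(text, spans$end[1] + 1L, spans$start[2]),
    spans$open[2], span_text(text, spans$start[2], spans$end[2]), spans$close[2],
    substr(text, spans$end[2] + 1L, nchar(text))
  )
}

#' Parse every check of an annotated corpus
#'
#' @param corpus Corpus tibble whose `text` column carries annotation markup.
#' @return A list with `corpus` (plain-text corpus tibble) and `annotations`
#'   (tibble of `check_id`, spans, and the gold `de_term` / `fn_term`
#'   surface strings).
#' @export
parse_annotated_corpus <- function(corpus) {
  parsed <- purrr::map(corpus$text, parse_annotation)
  plain <- corpus
  plain$text <- purrr::map_chr(parsed, "text")
  ann <- purrr::list_rbind(purrr::map(parsed, "annotation"))
  ann <- mutate(ann,
    check_id = corpus$check_id,
    de_term = span_text(plain$text, .data$de_start, .data$de_end),
    fn_term = span_text(plain$text, .data$fn_start, .data$fn_end),
    .before = 1
  )
  list(corpus = plain, annotations = ann)
}
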
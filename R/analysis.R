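# Descriptive analyses over indexed checks: per-domain frequency tables,
# the data-element-domain x function-domain pairing matrix, the Kahn
# harmonization cross-tabulation, and cross-network domain overlap.

domain_col <- function(kind) {
  if (match.arg(kind, construct_kinds()) == "data_element") "de_domain"
  else "fn_domain"
}

#' Per-domain frequency table
#'
#' Counts of checks per domain for one construct kind, with percentages.
#' `pct` keeps full precision; `pct_label` is rounded to the whole percent
#' for report-style display. Sorted by descending count.
#'
#' @param checks Indexed-check tibble from one network.
#' @param kind `"data_element"` or `"function"`.
#' @return Tibble `domain`, `n`, `pct`, `pct_label`; empty input gives an
#'   empty table, not an error.
#' @export
dq_frequency_table <- function(checks, kind) {
  col <- domain_col(kind)
  if (nrow(checks) == 0) {
    return(tibble(domain = character(), n = integer(), pct = double(),
                  pct_label = integer()))
  }
  if (length(unique(checks$network)) > 1) {
    abort("frequency tables are per network; filter the checks first")
  }
  checks |>
    count(domain = .data[[col]]) |>
    mutate(pct = 100 * .data$n / sum(.data$n),
           pct_label = as.integer(round(.data$pct))) |>
    arrange(desc(.data$n), .data$domain)
}

#' Data-element domain by function domain pairing matrix
#'
#' Cell (d, f) counts the checks whose data element fell in domain d and
#' whose function fell in domain f. [uncategorized()] rows/columns are kept
#' and flagged, never silently dropped.
#'
#' @param checks Indexed-check tibble.
#' @return Object of class `dq_pairing_matrix` with `cells` (long tibble),
#'   `de_totals`, `fn_totals`, `n_total` and `n_uncategorized`. `tidy()`
#'   returns the cells, `glance()` the totals, `autoplot()` a heat map and
#'   `as.matrix()` the dense matrix (rows = data-element domains).
#' @export
dq_pairing_matrix <- function(checks) {
  cells <- checks |>
    count(.data$de_domain, .data$fn_domain) |>
    arrange(.data$de_domain, .data$fn_domain)
  structure(
    list(
      cells = cells,
      de_totals = checks |> count(.data$de_domain, name = "total") |>
        arrange(.data$de_domain),
      fn_totals = checks |> count(.data$fn_domain, name = "total") |>
        arrange(.data$fn_domain),
      n_total = nrow(checks),
      n_uncategorized = sum(checks$de_domain == uncategorized() |
                              checks$fn_domain == uncategorized())
    ),
    class = "dq_pairing_matrix"
  )
}

#' @export
print.dq_pairing_matrix <- function(x, ...) {
  cat(sprintf("<dq_pairing_matrix> %d checks, %d x %d domains", x$n_total,
              nrow(x$de_totals), nrow(x$fn_totals)))
  if (x$n_uncategorized > 0) {
    cat(sprintf(" (%d with an UNCATEGORIZED construct)", x$n_uncategorized))
  }
  cat("\n")
  print(as.matrix(x))
  invisible(x)
}

#' @export
as.matrix.dq_pairing_matrix <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$cells, names_from = "fn_domain",
                             values_from = "n", values_fill = 0L)
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$de_domain
  m[order(rownames(m)), order(colnames(m)), drop = FALSE]
}

#' @export
tidy.dq_pairing_matrix <- function(x, ...) x$cells

#' @export
glance.dq_pairing_matrix <- function(x, ...) {
  top <- x$cells |> arrange(desc(.data$n)) |> slice(1)
  tibble(
    n_checks = x$n_total, n_de_domains = nrow(x$de_totals),
    n_fn_domains = nrow(x$fn_totals),
    n_uncategorized = x$n_uncategorized,
    top_pair = paste0(top$de_domain, "-", top$fn_domain),
    top_pair_n = top$n
  )
}

#' @rdname dq_pairing_matrix
#' @param object A `dq_pairing_matrix`.
#' @param ... Unused.
#' @export
autoplot.dq_pairing_matrix <- function(object, ...) {
  ggplot2::ggplot(object$cells,
                  ggplot2::aes(.data$fn_domain, .data$de_domain,
                               fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "#f7fbff", high = "#08519c") +
    ggplot2::labs(x = "Function domain", y = "Data element domain",
                  fill = "Checks") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Write a pairing matrix as a dense CSV table
#'
#' @param x A `dq_pairing_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairing_matrix <- function(x, path) {
  m <- as.matrix(x)
  readr::write_csv(
    bind_rows(
      as_tibble(cbind(tibble(de_domain = rownames(m)), as.data.frame(m)))
    ),
    path
  )
  invisible(path)
}

#' Domain by harmonization-category cross-tabulation
#'
#' Counts of checks per (domain, Kahn subcategory) for one construct kind.
#' Harmonization labels are external inputs; checks without a label are
#' reported separately, and an unknown label is an error naming the value.
#'
#' @param checks Indexed-check tibble.
#' @param kind Construct kind whose domains form the rows.
#' @return Object of class `dq_crosstab`: `cells` (long tibble `domain`,
#'   `category`, `n`), `unlabeled` (per-domain counts of unlabeled checks),
#'   `kind`. `tidy()` returns the cells.
#' @export
dq_harmonization_crosstab <- function(checks, kind) {
  col <- domain_col(kind)
  lab <- checks[!is.na(checks$harmonization), ]
  bad <- setdiff(unique(lab$harmonization), harmonization_categories())
  if (length(bad)) {
    abort(sprintf("unknown harmonization label(s): %s",
                  paste(bad, collapse = ", ")))
  }
  structure(
    list(
      cells = lab |>
        count(domain = .data[[col]], category = .data$harmonization) |>
        arrange(.data$domain, .data$category),
      unlabeled = checks[is.na(checks$harmonization), ] |>
        count(domain = .data[[col]]),
      kind = match.arg(kind, construct_kinds())
    ),
    class = "dq_crosstab"
  )
}

#' @export
print.dq_crosstab <- function(x, ...) {
  cat(sprintf("<dq_crosstab> %s domains x harmonization categories (%d labeled, %d unlabeled checks)\n",
              x$kind, sum(x$cells$n), sum(x$unlabeled$n)))
  print(x$cells, n = 20)
  invisible(x)
}

#' @export
tidy.dq_crosstab <- function(x, ...) x$cells

#' Cross-network domain overlap
#'
#' Exact name-match intersection of two taxonomies' domain sets for one
#' construct kind, after canonical spelling normalization that collapses
#' only trivial singular/plural variants ("Observation" vs "Observations").
#' Semantic near-matches (an insurance-specific domain vs a broader
#' socioeconomic one, age vs birth) are deliberately *not* collapsed: they
#' are associated but do not refer to the same meaning.
#'
#' @param tax_a,tax_b Two `dq_taxonomy` objects.
#' @param kind Construct kind to compare.
#' @return Object of class `dq_overlap` with `shared`, `only_a`, `only_b`
#'   (character vectors of domain names, spelled as in `tax_a` where
#'   shared) and the two network tags. `tidy()` gives one row per domain
#'   with its membership.
#' @export
dq_domain_overlap <- function(tax_a, tax_b, kind) {
  kind <- match.arg(kind, construct_kinds())
  dom <- function(tax) {
    sort(unique(tax$entries$domain[tax$entries$construct_kind == kind]))
  }
  canon <- function(x) {
    # collapse trivial plural variants of the final word only
    tolower(sub("(?<=[a-z])s$", "", x, perl = TRUE))
  }
  a <- dom(tax_a); b <- dom(tax_b)
  shared <- a[canon(a) %in% canon(b)]
  structure(
    list(
      shared = shared,
      only_a = a[!canon(a) %in% canon(b)],
      only_b = b[!canon(b) %in% canon(a)],
      network_a = tax_a$network, network_b = tax_b$network, kind = kind
    ),
    class = "dq_overlap"
  )
}

#' @export
print.dq_overlap <- function(x, ...) {
  cat(sprintf("<dq_overlap> %s domains, %s vs %s\n", x$kind, x$network_a,
              x$network_b))
  cat("  shared:", paste(x$shared, collapse = ", "), "\n")
  cat(sprintf("  only %s:", x$network_a),
      paste(x$only_a, collapse = ", "), "\n")
  cat(sprintf("  only %s:", x$network_b),
      paste(x$only_b, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.dq_overlap <- function(x, ...) {
  bind_rows(
    tibble(domain = x$shared, membership = "shared"),
    tibble(domain = x$only_a, membership = paste0("only_", x$network_a)),
    tibble(domain = x$only_b, membership = paste0("only_", x$network_b))
  )
}
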
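indexed_fixture <- function() {
  tibble::tibble(
    check_id = sprintf("c%d", 1:6), network = "OHDSI",
    de_term = c("persons", "persons", "age", "refills", "persons", "visits"),
    de_domain = c("Person", "Person", "Age", "Medication", "Person", "Visit"),
    fn_term = c("number of", "number of", "distribution of", "number of",
                "number of", "length of"),
    fn_domain = c("Count", "Count", "Distribution", "Count", "Count",
                  "Time Length"),
    harmonization = c("Plausibility-Atemporal", "Plausibility-Temporal",
                      "Plausibility-Atemporal", "Plausibility-Atemporal",
                      NA, "Conformance-Calculation")
  )
}

test_that("frequency tables count, rank and percentage per domain", {
  ft <- dq_frequency_table(indexed_fixture(), "data_element")
  expect_equal(ft$domain[1], "Person")
  expect_equal(ft$n[1], 3)
  expect_equal(ft$pct[1], 50)
  expect_equal(sum(ft$n), 6)

  one <- dq_frequency_table(indexed_fixture()[1, ], "function")
  expect_equal(one$pct, 100)

  empty <- dq_frequency_table(indexed_fixture()[0, ], "data_element")
  expect_equal(nrow(empty), 0)
})

test_that("counts are conserved across frequency tables and the pairing matrix", {
  checks <- replica_gen("OHDSI")$indexed
  ft_de <- dq_frequency_table(checks, "data_element")
  ft_fn <- dq_frequency_table(checks, "function")
  pm <- dq_pairing_matrix(checks)
  expect_equal(sum(ft_de$n), nrow(checks))
  expect_equal(sum(ft_fn$n), nrow(checks))
  expect_equal(sum(pm$cells$n), nrow(checks))
  expect_equal(sum(as.matrix(pm)), nrow(checks))
  # percentages sum to 100 within rounding slack
  expect_lte(abs(sum(ft_de$pct_label) - 100), nrow(ft_de) / 2)
  # margins agree with the frequency tables
  m <- as.matrix(pm)
  expect_equal(rowSums(m)[ft_de$domain], setNames(as.double(ft_de$n),
                                                  ft_de$domain))
  expect_equal(colSums(m)[ft_fn$domain], setNames(as.double(ft_fn$n),
                                                  ft_fn$domain))
})

test_that("a single check yields a single-cell matrix with unit margins", {
  pm <- dq_pairing_matrix(indexed_fixture()[1, ])
  expect_equal(pm$cells$n, 1)
  expect_equal(pm$n_total, 1)
  expect_equal(unname(as.matrix(pm)[1, 1]), 1)
  expect_equal(glance(pm)$top_pair, "Person-Count")
})

test_that("UNCATEGORIZED constructs are kept and flagged in the matrix", {
  checks <- indexed_fixture()
  checks$de_domain[2] <- uncategorized()
  pm <- dq_pairing_matrix(checks)
  expect_equal(pm$n_uncategorized, 1)
  expect_true(uncategorized() %in% pm$cells$de_domain)
  expect_equal(sum(pm$cells$n), nrow(checks))
})

test_that("the harmonization crosstab separates unlabeled checks and rejects bad labels", {
  ct <- dq_harmonization_crosstab(indexed_fixture(), kind = "function")
  expect_equal(sum(ct$cells$n) + sum(ct$unlabeled$n), 6)
  # a function domain used for exactly one category occupies a single column
  tl <- ct$cells[ct$cells$domain == "Time Length", ]
  expect_equal(tl$category, "Conformance-Calculation")
  expect_equal(ct$unlabeled$domain, "Count")

  none <- indexed_fixture()
  none$harmonization <- NA_character_
  ct0 <- dq_harmonization_crosstab(none, kind = "data_element")
  expect_equal(nrow(ct0$cells), 0)
  expect_equal(sum(ct0$unlabeled$n), 6)

  bad <- indexed_fixture()
  bad$harmonization[1] <- "Made-Up"
  expect_error(dq_harmonization_crosstab(bad, kind = "function"), "Made-Up")
})

test_that("crosstab row sums equal each domain's labeled check count", {
  checks <- replica_gen("OHDSI")$indexed
  ct <- dq_harmonization_crosstab(checks, kind = "function")
  by_dom <- tapply(ct$cells$n, ct$cells$domain, sum)
  labeled <- checks[!is.na(checks$harmonization), ]
  expect_equal(as.integer(by_dom[names(by_dom)]),
               as.integer(table(labeled$fn_domain)[names(by_dom)]))
})

test_that("domain overlap is symmetric, identity-complete, and plural-insensitive", {
  tax_o <- ohdsi_taxonomy()
  tax_c <- cesr_taxonomy()
  ab <- dq_domain_overlap(tax_o, tax_c, "data_element")
  ba <- dq_domain_overlap(tax_c, tax_o, "data_element")
  expect_setequal(ab$shared, ba$shared)

  self <- dq_domain_overlap(tax_o, tax_o, "data_element")
  expect_length(self$only_a, 0)
  expect_length(self$only_b, 0)
  expect_equal(length(self$shared), 12)

  # trivial plural variants collapse; semantic near-matches never do
  a <- dq_taxonomy(tibble::tibble(network = "OTHER",
                                  construct_kind = "data_element",
                                  term = "x", domain = "Observation",
                                  definition = "d"))
  b <- dq_taxonomy(tibble::tibble(network = "OTHER",
                                  construct_kind = "data_element",
                                  term = "y", domain = "Observations",
                                  definition = "d"))
  expect_equal(dq_domain_overlap(a, b, "data_element")$shared, "Observation")
  expect_false("Insurance" %in% ab$shared)
  expect_false("Age" %in% ab$shared)
  expect_equal(nrow(tidy(ab)),
               length(c(ab$shared, ab$only_a, ab$only_b)))
})

test_that("the pairing heat map is a ggplot object", {
  expect_s3_class(ggplot2::autoplot(dq_pairing_matrix(indexed_fixture())),
                  "ggplot")
})
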
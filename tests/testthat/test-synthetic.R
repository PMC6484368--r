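small_spec <- function(...) {
  dq_generator_spec(
    tibble::tibble(
      de_term = c("Persons", "visits"), de_domain = c("Person", "Visit"),
      fn_term = c("Number of", "Distribution of"),
      fn_domain = c("Count", "Distribution"), n = c(3L, 2L)
    ),
    network = "OHDSI", ...
  )
}

test_that("the generator emits exactly the specified marginal counts", {
  gen <- generate_corpus(small_spec(seed = 4))
  expect_equal(nrow(gen$corpus), 5)
  ft <- dq_frequency_table(gen$indexed, "data_element")
  expect_equal(ft$n[ft$domain == "Person"], 3)
  expect_equal(ft$n[ft$domain == "Visit"], 2)
  # gold annotations point at the marginal terms
  expect_setequal(unique(gen$annotations$de_term), c("Persons", "visits"))
})

test_that("generation is byte-identical under a fixed spec and seed", {
  a <- generate_corpus(small_spec(seed = 31))
  b <- generate_corpus(small_spec(seed = 31))
  expect_identical(a$corpus, b$corpus)
  expect_identical(a$annotations, b$annotations)
  c <- generate_corpus(small_spec(seed = 32))
  expect_false(identical(a$corpus$text, c$corpus$text))
})

test_that("a count-1 spec yields a single clean templated check", {
  spec <- dq_generator_spec(
    tibble::tibble(de_term = "Persons", de_domain = "Person",
                   fn_term = "Number of", fn_domain = "Count", n = 1L),
    network = "OHDSI", seed = 1, modifier_rate = 0
  )
  gen <- generate_corpus(spec)
  expect_equal(nrow(gen$corpus), 1)
  expect_match(gen$corpus$text,
               "^Number of Persons with at least one .+, by .+$")
})

test_that("modifier rate one prefixes every data element with a stoplist token", {
  gen <- generate_corpus(small_spec(seed = 2, modifier_rate = 1))
  mod_re <- sprintf("(%s) \\[\\[", paste(default_stoplist(), collapse = "|"))
  expect_true(all(grepl(mod_re, gen$annotated$text)))
  # the modifier is narrative only, never part of the gold span
  expect_false(any(grepl(paste(default_stoplist(), collapse = "|"),
                         gen$annotations$de_term)))
})

test_that("strict mode rejects marginal terms missing from the vocabulary", {
  voc <- ohdsi_taxonomy()$entries
  expect_error(
    dq_generator_spec(
      tibble::tibble(de_term = "made-up thing", de_domain = "Person",
                     fn_term = "Number of", fn_domain = "Count", n = 1L),
      network = "OHDSI", vocabulary = voc
    ),
    "absent from the vocabulary"
  )
  # all-known terms pass
  expect_s3_class(
    dq_generator_spec(
      tibble::tibble(de_term = "Persons", de_domain = "Person",
                     fn_term = "Number of", fn_domain = "Count", n = 1L),
      network = "OHDSI", vocabulary = voc
    ),
    "dq_generator_spec"
  )
})

test_that("gold-trained extraction recovers every slot of a clean corpus", {
  for (net in c("OHDSI", "CESR")) {
    gen <- generate_corpus(scale_spec(replica_spec(net), 60, seed = 13,
                                      modifier_rate = 0))
    model <- train_extractor(gen$corpus, gen$annotations)
    ev <- evaluate_extractor(model, gen$corpus, gen$annotations)
    expect_equal(ev$proportion_de, 1)
    expect_equal(ev$proportion_fn, 1)
  }
})

test_that("the synthesized CESR lexicon is cardinality-faithful", {
  lex <- generate_cesr_lexicon()
  expect_equal(nrow(lex), 702)
  expect_equal(length(unique(lex$domain)), 23)
  counts <- table(lex$domain)
  expect_equal(unname(counts[["Medication"]]), 120)
  meta <- cesr_de_domains()
  expect_equal(as.integer(counts[meta$domain]), meta$n_unique_terms)
  # printed sample terms are kept verbatim, placeholders are marked
  expect_true("encounter dates" %in% lex$term[!lex$synthetic])
  expect_true(all(grepl("_term_\\d+$", lex$term[lex$synthetic])))
})

test_that("lexicon synthesis honours printed-term edge cases", {
  meta <- tibble::tibble(domain = "Solo", n_unique_terms = 1L,
                         definition = "one-term domain")
  printed <- tibble::tibble(network = "CESR", construct_kind = "data_element",
                            term = "the term", domain = "Solo",
                            definition = "one-term domain")
  lex <- generate_cesr_lexicon(meta, printed)
  expect_equal(lex$term, "the term")
  expect_false(any(lex$synthetic))

  meta$n_unique_terms <- 0L
  expect_error(generate_cesr_lexicon(meta, printed), "exceed")
})

test_that("scaled specs keep totals and composition by largest remainder", {
  spec <- replica_spec("OHDSI")
  sc <- scale_spec(spec, 200, seed = 42)
  expect_equal(sum(sc$marginals$n), 200)
  # dominant cell keeps its share (55/172 of 200 ~ 64)
  person <- sum(sc$marginals$n[sc$marginals$de_domain == "Person"])
  expect_equal(person, round(55 / 172 * 200), tolerance = 0.03)
})

test_that("an all-zero spec warns and returns an empty corpus", {
  spec <- dq_generator_spec(
    tibble::tibble(de_term = "Persons", de_domain = "Person",
                   fn_term = "Number of", fn_domain = "Count", n = 0L),
    network = "OHDSI"
  )
  expect_warning(gen <- generate_corpus(spec), "empty")
  expect_equal(nrow(gen$corpus), 0)
})

test_that("generator specs round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "network: OHDSI", "seed: 3", "modifier_rate: 0.5",
    "marginals:",
    "  - {de_term: Persons, de_domain: Person, fn_term: Number of, fn_domain: Count, count: 4}"
  ), path)
  spec <- read_generator_spec(path)
  expect_equal(sum(spec$marginals$n), 4)
  expect_equal(spec$modifier_rate, 0.5)

  writeLines(c("replica: OHDSI", "n_checks: 40"), path)
  rep40 <- read_generator_spec(path)
  expect_equal(sum(rep40$marginals$n), 40)
  expect_error(read_generator_spec(file.path(tempdir(), "nope.yaml")),
               "not found")
})
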
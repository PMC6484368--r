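test_that("split_corpus sizes the training set per rounding rule, minimum one", {
  corp <- dq_corpus(sprintf("check %d", 1:172), network = "OHDSI")
  sp <- split_corpus(corp, 0.10, seed = 1)
  expect_equal(nrow(sp$train), 17)  # nearest, ties up
  expect_equal(nrow(sp$test), 155)
  expect_equal(nrow(split_corpus(corp, 0.10, seed = 1,
                                 round_mode = "up")$train), 18)
  expect_equal(nrow(split_corpus(corp, 0.10, seed = 1,
                                 round_mode = "down")$train), 17)

  ten <- dq_corpus(sprintf("c %d", 1:10))
  sp10 <- split_corpus(ten, 0.10, seed = 3)
  expect_equal(nrow(sp10$train), 1)
  expect_equal(nrow(sp10$test), 9)
  expect_error(split_corpus(ten[0, ], 0.5, 1), "empty")
})

test_that("split_corpus is a deterministic exhaustive partition", {
  corp <- dq_corpus(sprintf("check %d", 1:50))
  a <- split_corpus(corp, 0.3, seed = 11)
  b <- split_corpus(corp, 0.3, seed = 11)
  expect_identical(a, b)
  expect_length(intersect(a$train$check_id, a$test$check_id), 0)
  expect_setequal(c(a$train$check_id, a$test$check_id), corp$check_id)
  expect_false(identical(a$train$check_id,
                         split_corpus(corp, 0.3, seed = 12)$train$check_id))
})

test_that("training learns lexicon terms and is order- and duplicate-invariant", {
  parsed <- parse_annotated_corpus(tiny_annotated())
  model <- train_extractor(parsed$corpus, parsed$annotations)
  de_terms <- model$lexicon$term[model$lexicon$kind == "data_element"]
  fn_terms <- model$lexicon$term[model$lexicon$kind == "function"]
  expect_true(all(c("persons", "visit records", "age") %in% de_terms))
  expect_true(all(c("number of", "distribution of", "length of") %in% fn_terms))

  # set semantics: duplicated and reordered annotations give the same model
  dup <- parse_annotated_corpus(tiny_annotated())
  dup$annotations <- dplyr::bind_rows(dup$annotations,
                                      dup$annotations)[c(5, 3, 1, 2, 4, 8, 6, 7), ]
  expect_equal(train_extractor(dup$corpus, dup$annotations), model)

  expect_error(train_extractor(parsed$corpus, parsed$annotations[0, ]),
               "zero annotations")
})

test_that("extraction recovers the worked examples", {
  parsed <- parse_annotated_corpus(tiny_annotated())
  model <- train_extractor(parsed$corpus, parsed$annotations)
  corp <- dq_corpus(
    "Number of persons with at least one drug occurrence, by drug_concept_id",
    network = "OHDSI", check_id = "fig1"
  )
  recs <- extract_constructs(model, corp)
  expect_equal(recs$term[recs$kind == "data_element"], "persons")
  expect_equal(recs$term[recs$kind == "function"], "Number of")
  expect_true(all(recs$confidence_flag == "MATCHED"))
})

test_that("context templates generalize to unseen terms and skip stoplist modifiers", {
  parsed <- parse_annotated_corpus(tiny_annotated())
  model <- train_extractor(parsed$corpus, parsed$annotations)
  corp <- dq_corpus(
    c("Number of care sites with at least one drug occurrence, by site",
      "Number of distinct providers with at least one drug occurrence, by year"),
    network = "OHDSI"
  )
  recs <- extract_constructs(model, corp)
  de <- recs[recs$kind == "data_element", ]
  expect_equal(de$term[1], "care sites")
  expect_equal(de$term[2], "providers")  # "distinct" is not the data element
  expect_equal(unique(recs$term[recs$kind == "function"]), "Number of")
})

test_that("a check with no candidates yields UNKNOWN records, never an error", {
  parsed <- parse_annotated_corpus(tiny_annotated())
  model <- train_extractor(parsed$corpus, parsed$annotations)
  recs <- extract_constructs(model, dq_corpus("lorem ipsum dolor sit amet",
                                              network = "OHDSI"))
  expect_equal(nrow(recs), 2)
  expect_setequal(recs$kind, construct_kinds())
  expect_true(all(recs$confidence_flag == "UNKNOWN"))
  expect_true(all(recs$term == ""))
})

test_that("evaluation computes proportion correct and lists every miss", {
  parsed <- parse_annotated_corpus(tiny_annotated())
  model <- train_extractor(parsed$corpus, parsed$annotations)
  ev <- evaluate_extractor(model, parsed$corpus, parsed$annotations)
  expect_equal(ev$proportion_de, 1)
  expect_equal(ev$proportion_fn, 1)
  expect_equal(nrow(ev$misses), 0)
  expect_equal(tidy(ev)$proportion, c(1, 1))

  # a model with no applicable knowledge misses everything
  other <- parse_annotated_corpus(patternless_annotated(3))
  stranger <- train_extractor(other$corpus, other$annotations,
                              network = "OHDSI")
  ev0 <- evaluate_extractor(stranger, parsed$corpus, parsed$annotations)
  expect_equal(ev0$proportion_de, 0)
  expect_equal(ev0$proportion_fn, 0)
  expect_equal(nrow(ev0$misses), 2 * ev0$n_checks)

  # partial correctness is plain arithmetic over the evaluated subset
  ev_sub <- evaluate_extractor(model, parsed$corpus, parsed$annotations[1:3, ])
  expect_equal(ev_sub$n_checks, 3)
  expect_equal(ev_sub$proportion_de, ev_sub$n_correct_de / 3)
})

test_that("models serialize to JSON and reload identically", {
  parsed <- parse_annotated_corpus(tiny_annotated())
  model <- train_extractor(parsed$corpus, parsed$annotations)
  path <- withr::local_tempfile(fileext = ".json")
  write_extraction_model(model, path)
  back <- read_extraction_model(path)
  expect_equal(back, model)
  expect_error(read_extraction_model(withr::local_tempfile(
    lines = "{\"format\": \"other\"}", fileext = ".json")), "not a dqindexr")
})

test_that("the iterative loop converges on a templated corpus and grows its subset", {
  gen <- generate_corpus(scale_spec(replica_spec("OHDSI"), 80,
                                    modifier_rate = 0, seed = 5))
  run <- iterative_train(gen$corpus, gen$annotations,
                         initial_subset_size = 8, threshold = 0.9,
                         max_iterations = 10, seed = 2)
  expect_true(run$converged)
  final <- run$trace[[length(run$trace)]]
  expect_gte(final$proportion_de, 0.9)
  expect_gte(final$proportion_fn, 0.9)
  tr <- tidy(run)
  expect_equal(tr$iteration, seq_len(nrow(tr)))
  # the annotated subset grows strictly with every extra iteration
  if (length(run$trace) > 1) {
    expect_gt(length(run$annotated_ids), 8)
  } else {
    expect_length(run$annotated_ids, 8)
  }

  # determinism: same seed, same run
  run2 <- iterative_train(gen$corpus, gen$annotations,
                          initial_subset_size = 8, threshold = 0.9,
                          max_iterations = 10, seed = 2)
  expect_equal(tidy(run2), tr)
  expect_equal(run2$model, run$model)
})

test_that("threshold zero terminates after a single iteration", {
  gen <- generate_corpus(scale_spec(replica_spec("OHDSI"), 20, seed = 9))
  run <- iterative_train(gen$corpus, gen$annotations,
                         initial_subset_size = 2, threshold = 1e-9,
                         max_iterations = 10, seed = 1)
  expect_length(run$trace, 1)
  expect_true(run$converged)
})

test_that("a patternless corpus triggers the non-convergence signal", {
  parsed <- parse_annotated_corpus(patternless_annotated(6))
  expect_warning(
    run <- iterative_train(parsed$corpus, parsed$annotations,
                           initial_subset_size = 1, threshold = 0.9,
                           max_iterations = 1, seed = 1),
    class = "dqindexr_nonconvergence"
  )
  expect_false(run$converged)
  expect_lt(run$trace[[1]]$proportion_de, 1)
  expect_equal(glance(run)$converged, FALSE)
})
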
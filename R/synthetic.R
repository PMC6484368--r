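# Template-based synthetic DQ-check corpora.
#
# The generator emits gold-annotated checks in the two network dialects so
# that every other module is testable without the (partly proprietary) real
# corpora: aggregate post-ETL characterization phrasing for OHDSI ("Number
# of persons with at least one drug occurrence, by drug_concept_id") and
# variable-level intrinsic verification phrasing for CESR ("check that
# birth date is not missing", "the count of encounter dates by year across
# all years of data"). Marginal domain counts are configurable; replica
# specs reproduce the published per-domain counts of both networks.

ohdsi_fillers <- function() {
  c("drug occurrence", "condition occurrence", "procedure occurrence",
    "measurement result")
}

ohdsi_stratifiers <- function() {
  c("drug_concept_id", "condition_concept_id", "year", "site")
}

#' Build a generator specification
#'
#' @param marginals Tibble with columns `de_term`, `de_domain`, `fn_term`,
#'   `fn_domain`, `n` (checks to emit per row) and optionally
#'   `harmonization`.
#' @param network Dialect whose templates are used.
#' @param seed Integer seed; generation is byte-identical for a fixed
#'   spec + seed.
#' @param modifier_rate Probability that a stoplist modifier (e.g.
#'   "distinct") is inserted before the data element — a stress input for
#'   the extractor; 0 emits clean templated checks.
#' @param stratifier_rate Probability that an OHDSI-style check carries a
#'   trailing stratification clause ("by drug_concept_id"). Stratification
#'   clauses are narrative distractors only: they are never part of either
#'   gold span.
#' @param vocabulary Optional vocabulary tibble used to validate terms when
#'   `strict = TRUE`.
#' @param strict Error on marginal terms absent from `vocabulary`.
#' @return An object of class `dq_generator_spec`.
#' @export
dq_generator_spec <- function(marginals, network, seed = 1L,
                              modifier_rate = 0, stratifier_rate = 1,
                              vocabulary = NULL, strict = !is.null(vocabulary)) {
  required <- c("de_term", "de_domain", "fn_term", "fn_domain", "n")
  missing <- setdiff(required, names(marginals))
  if (length(missing)) {
    abort(sprintf("marginals lack column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  marginals <- as_tibble(marginals)
  if (!"harmonization" %in% names(marginals)) {
    marginals$harmonization <- NA_character_
  }
  marginals$n <- as.integer(marginals$n)
  if (any(marginals$n < 0)) abort("marginal counts must be non-negative")
  if (strict) {
    if (is.null(vocabulary)) abort("strict mode needs a vocabulary")
    vkey <- paste(term_key(vocabulary$term), vocabulary$construct_kind)
    mkey <- c(paste(term_key(marginals$de_term), "data_element"),
              paste(term_key(marginals$fn_term), "function"))
    absent <- setdiff(mkey, vkey)
    if (length(absent)) {
      abort(sprintf("marginal term(s) absent from the vocabulary: %s",
                    paste(absent, collapse = "; ")))
    }
  }
  structure(
    list(network = network, seed = as.integer(seed),
         modifier_rate = modifier_rate, stratifier_rate = stratifier_rate,
         marginals = marginals),
    class = "dq_generator_spec"
  )
}

#' @export
print.dq_generator_spec <- function(x, ...) {
  cat(sprintf(
    "<dq_generator_spec> %s: %d checks over %d marginal rows (modifier rate %.2f, stratifier rate %.2f, seed %d)\n",
    x$network, sum(x$marginals$n), nrow(x$marginals), x$modifier_rate,
    x$stratifier_rate, x$seed
  ))
  invisible(x)
}

ohdsi_template <- function(fn, de, filler, strat, mod, with_strat) {
  body <- switch(fn$fn_domain,
    Count = sprintf("{{ %s }} %s[[ %s ]] with at least one %s",
                    fn$fn_term, mod, de, filler),
    sprintf("{{ %s }} %s[[ %s ]]", fn$fn_term, mod, de)
  )
  strat_clause <- switch(fn$fn_domain,
    Count = sprintf(", by %s", strat),
    sprintf(" by %s", strat)
  )
  if (with_strat) paste0(body, strat_clause) else body
}

cesr_template <- function(fn, de, mod) {
  de_m <- paste0(mod, "[[ ", de, " ]]")
  switch(fn$fn_domain,
    Missing = sprintf("check that %s is not {{ %s }}", de_m, fn$fn_term),
    Existence = sprintf("confirm the {{ %s }} of %s in the table",
                        fn$fn_term, de_m),
    Count = sprintf("the {{ %s }} of %s by year across all years of data",
                    fn$fn_term, de_m),
    Trend = sprintf("examine the {{ %s }} of %s across all years of data",
                    fn$fn_term, de_m),
    Sum = sprintf("the {{ %s }} of %s values must add to 1",
                  fn$fn_term, de_m),
    Uniqueness = sprintf("check {{ %s }} of %s entries", fn$fn_term, de_m),
    `Variable Type` = ,
    `Variable Length` = ,
    Category = sprintf("verify %s variable {{ %s }}", de_m, fn$fn_term),
    sprintf("perform the {{ %s }} check on %s", fn$fn_term, de_m)
  )
}

#' Generate a gold-annotated synthetic corpus
#'
#' Emits exactly `n` checks per marginal row, rendered through the
#' network's narrative templates, each paired with its gold annotation.
#' Byte-identical output for a fixed spec + seed.
#'
#' @param spec A `dq_generator_spec`.
#' @param seed Overrides `spec$seed` if given.
#' @return A list of class `dq_synthetic_corpus`:
#'   * `corpus` — plain-text corpus tibble,
#'   * `annotations` — gold spans + terms (see [parse_annotated_corpus()]),
#'   * `annotated` — the corpus with markup in `text`,
#'   * `indexed` — the gold indexed-check tibble (the generator knows its
#'     own slots).
#' @export
generate_corpus <- function(spec, seed = NULL) {
  seed <- seed %||% spec$seed
  rows <- spec$marginals[rep(seq_len(nrow(spec$marginals)),
                             spec$marginals$n), ]
  if (nrow(rows) == 0) {
    warning("generator spec emits an empty corpus")
    empty <- dq_corpus("placeholder", spec$network)[0, ]
    return(structure(list(corpus = empty, annotations = tibble(),
                          annotated = empty, indexed = tibble()),
                     class = "dq_synthetic_corpus"))
  }
  n <- nrow(rows)
  withr::with_seed(seed, {
    rows <- rows[sample.int(n), ]
    mods <- ifelse(stats::runif(n) < spec$modifier_rate,
                   paste0(sample(default_stoplist(), n, replace = TRUE), " "),
                   "")
    strats <- sample(ohdsi_stratifiers(), n, replace = TRUE)
    fillers <- sample(ohdsi_fillers(), n, replace = TRUE)
    with_strat <- stats::runif(n) < spec$stratifier_rate
  })
  text <- vapply(seq_len(n), function(i) {
    fn <- list(fn_term = rows$fn_term[i], fn_domain = rows$fn_domain[i])
    if (spec$network == "OHDSI") {
      ohdsi_template(fn, rows$de_term[i], fillers[i], strats[i], mods[i],
                     with_strat[i])
    } else {
      cesr_template(fn, rows$de_term[i], mods[i])
    }
  }, character(1))
  ids <- sprintf("%s_%0*d", tolower(spec$network), nchar(n), seq_len(n))
  annotated <- dq_corpus(text, network = spec$network, check_id = ids,
                         harmonization = rows$harmonization)
  parsed <- parse_annotated_corpus(annotated)
  indexed <- tibble(
    check_id = ids, network = spec$network,
    de_term = rows$de_term, de_domain = rows$de_domain,
    fn_term = rows$fn_term, fn_domain = rows$fn_domain,
    harmonization = rows$harmonization
  )
  structure(
    list(corpus = parsed$corpus, annotations = parsed$annotations,
         annotated = annotated, indexed = indexed),
    class = "dq_synthetic_corpus"
  )
}

#' @export
print.dq_synthetic_corpus <- function(x, ...) {
  cat(sprintf("<dq_synthetic_corpus> %d checks (%s)\n", nrow(x$corpus),
              paste(unique(x$corpus$network), collapse = ", ")))
  invisible(x)
}

#' Synthesize a cardinality-faithful CESR data-element lexicon
#'
#' The full CESR data-element term list is proprietary; only per-domain
#' sample terms and per-domain unique-term cardinalities are published.
#' This builds a synthetic stand-in vocabulary: all printed sample terms
#' plus clearly marked placeholder terms (`<domain>_term_<k>`) until each
#' domain reaches its published cardinality, 702 terms in total.
#'
#' @param cardinalities Tibble `domain`, `n_unique_terms` (default: the
#'   packaged published values, [cesr_de_domains()]).
#' @param printed_terms Vocabulary tibble of printed sample terms (default:
#'   the packaged sample file).
#' @param seed Accepted for interface symmetry; synthesis is deterministic.
#' @return Vocabulary tibble (`network`, `construct_kind`, `term`,
#'   `domain`, `definition`, `synthetic`) loadable via [dq_taxonomy()].
#' @export
generate_cesr_lexicon <- function(cardinalities = NULL, printed_terms = NULL,
                                  seed = NULL) {
  meta <- cardinalities %||% cesr_de_domains()
  printed <- printed_terms %||% readr::read_csv(
    system.file("extdata", "cesr_de_sample_vocabulary.csv",
                package = "dqindexr"),
    col_types = readr::cols(.default = "c"), na = character()
  )
  defs <- if ("definition" %in% names(meta)) {
    distinct(meta, .data$domain, .data$definition)
  } else {
    distinct(printed, .data$domain, .data$definition)
  }
  purrr::list_rbind(purrr::map(seq_len(nrow(meta)), function(i) {
    dom <- meta$domain[i]
    card <- meta$n_unique_terms[i]
    have <- printed[printed$domain == dom, ]
    if (nrow(have) > card) {
      abort(sprintf(
        "domain %s: %d printed terms exceed the published cardinality %d",
        dom, nrow(have), card
      ))
    }
    k <- card - nrow(have)
    slug <- gsub("[^a-z0-9]+", "_", tolower(dom))
    extra <- if (k > 0) {
      tibble(
        network = "CESR", construct_kind = "data_element",
        term = sprintf("%s_term_%d", slug, seq_len(k)), domain = dom,
        definition = defs$definition[defs$domain == dom][1]
      )
    } else {
      NULL
    }
    bind_rows(mutate(have, synthetic = FALSE),
              if (!is.null(extra)) mutate(extra, synthetic = TRUE))
  }))
}

# Deterministic greedy transport: distribute the de x fn joint mass so
# that both marginals hold exactly, with published cells pinned first and
# the remainder filled over alphabetically ordered domains.
build_pairing_cells <- function(de_marginals, fn_marginals,
                                pinned = NULL) {
  de <- arrange(de_marginals, .data$domain)
  fn <- arrange(fn_marginals, .data$domain)
  if (sum(de$n) != sum(fn$n)) {
    abort("data-element and function marginals must have equal totals")
  }
  de_rem <- stats::setNames(as.integer(de$n), de$domain)
  fn_rem <- stats::setNames(as.integer(fn$n), fn$domain)
  cells <- list()
  if (!is.null(pinned) && nrow(pinned) > 0) {
    for (i in seq_len(nrow(pinned))) {
      d <- pinned$de_domain[i]; f <- pinned$fn_domain[i]
      n <- as.integer(pinned$n[i])
      if (!d %in% names(de_rem) || !f %in% names(fn_rem)) {
        abort(sprintf("pinned pair %s-%s names an unknown domain", d, f))
      }
      if (de_rem[d] < n || fn_rem[f] < n) {
        abort(sprintf("pinned pair %s-%s (%d) exceeds a marginal", d, f, n))
      }
      de_rem[d] <- de_rem[d] - n
      fn_rem[f] <- fn_rem[f] - n
      cells[[length(cells) + 1L]] <-
        tibble(de_domain = d, fn_domain = f, n = n, pinned = TRUE)
    }
  }
  pinned_key <- if (!is.null(pinned) && nrow(pinned) > 0) {
    paste(pinned$de_domain, pinned$fn_domain)
  } else {
    character()
  }
  for (d in names(de_rem)) {
    for (f in names(fn_rem)) {
      if (de_rem[d] == 0L) break
      # pinned cells hold exactly their published value
      if (paste(d, f) %in% pinned_key) next
      take <- min(de_rem[d], fn_rem[f])
      if (take > 0L) {
        de_rem[d] <- de_rem[d] - take
        fn_rem[f] <- fn_rem[f] - take
        cells[[length(cells) + 1L]] <-
          tibble(de_domain = d, fn_domain = f, n = take, pinned = FALSE)
      }
    }
  }
  bind_rows(cells) |>
    group_by(.data$de_domain, .data$fn_domain) |>
    summarise(n = sum(.data$n), pinned = any(.data$pinned),
              .groups = "drop") |>
    arrange(.data$de_domain, .data$fn_domain)
}

# Expand domain-level cells to per-check term assignments: terms are
# assigned round-robin in vocabulary order within each domain, so domain
# marginals are exact and term usage is spread deterministically.
assign_terms <- function(cells, de_vocab, fn_vocab, rules = NULL) {
  checks <- cells[rep(seq_len(nrow(cells)), cells$n),
                  c("de_domain", "fn_domain")]
  checks <- checks |>
    group_by(.data$de_domain) |>
    mutate(de_term = {
      terms <- de_vocab$term[de_vocab$domain == .data$de_domain[1]]
      if (length(terms) == 0) {
        abort(sprintf("no vocabulary terms for data-element domain %s",
                      .data$de_domain[1]))
      }
      rep(terms, length.out = n())
    }) |>
    ungroup() |>
    group_by(.data$fn_domain) |>
    mutate(fn_term = {
      terms <- fn_vocab$term[fn_vocab$domain == .data$fn_domain[1]]
      if (length(terms) == 0) {
        abort(sprintf("no vocabulary terms for function domain %s",
                      .data$fn_domain[1]))
      }
      rep(terms, length.out = n())
    },
    harmonization = {
      cats <- NA_character_
      if (!is.null(rules) && .data$fn_domain[1] %in% names(rules)) {
        cats <- rules[[.data$fn_domain[1]]]
      }
      rep(cats, length.out = n())
    }) |>
    ungroup()
  checks |>
    count(.data$de_term, .data$de_domain, .data$fn_term, .data$fn_domain,
          .data$harmonization, name = "n")
}

read_replica_yaml <- function(network) {
  path <- system.file(
    "extdata", sprintf("replica_%s.yaml", tolower(network)),
    package = "dqindexr"
  )
  yaml::read_yaml(path)
}

# YAML record list -> tibble; the count key is spelled `count` in the
# packaged files (a bare `n` is a YAML 1.1 boolean) and renamed here.
yaml_tbl <- function(x) {
  out <- purrr::list_rbind(purrr::map(x, as_tibble))
  if ("count" %in% names(out)) out <- rename(out, n = "count")
  out
}

#' Replica generator spec for a network
#'
#' Builds the generator spec whose domain-level frequency tables reproduce
#' the published per-domain check counts of the network (172 checks for
#' OHDSI, 3,434 for CESR) and whose pairing matrix reproduces the
#' individually published cells; the remaining joint mass is filled by a
#' deterministic greedy rule. For CESR the data-element terms come from the
#' cardinality-faithful synthesized lexicon.
#'
#' @param network `"OHDSI"` or `"CESR"`.
#' @param seed Generation seed stored on the spec.
#' @param cesr_lexicon Optional pre-built CESR data-element vocabulary.
#' @return A `dq_generator_spec`.
#' @export
replica_spec <- function(network = c("OHDSI", "CESR"), seed = 1L,
                         cesr_lexicon = NULL) {
  network <- match.arg(network)
  raw <- read_replica_yaml(network)
  de_m <- yaml_tbl(raw$de_marginals)
  fn_m <- yaml_tbl(raw$fn_marginals)
  pins <- yaml_tbl(raw$pinned_pairs)
  rules <- stats::setNames(
    purrr::map(raw$harmonization_rules, ~ unlist(.x$categories)),
    purrr::map_chr(raw$harmonization_rules, "fn_domain")
  )
  if (network == "OHDSI") {
    voc <- ohdsi_taxonomy()$entries
    de_vocab <- filter(voc, .data$construct_kind == "data_element")
    fn_vocab <- filter(voc, .data$construct_kind == "function")
  } else {
    de_vocab <- cesr_lexicon %||% generate_cesr_lexicon()
    fn_vocab <- filter(cesr_taxonomy()$entries,
                       .data$construct_kind == "function")
  }
  cells <- build_pairing_cells(de_m, fn_m, pins)
  marginals <- assign_terms(cells, de_vocab, fn_vocab, rules)
  dq_generator_spec(
    marginals, network = network, seed = seed,
    modifier_rate = raw$modifier_rate %||% 0,
    stratifier_rate = raw$stratifier_rate %||% 1
  )
}

#' Scale a generator spec to a different corpus size
#'
#' Deterministic systematic (every k-th) sampling over the expanded check
#' list, so small stress corpora keep (approximately) the joint
#' composition even when the marginals are fragmented into many
#' single-check term rows; sizes beyond the original total replicate the
#' whole spec first.
#'
#' @param spec A `dq_generator_spec`.
#' @param n Target corpus size.
#' @param modifier_rate,stratifier_rate,seed Optionally override the
#'   spec's settings.
#' @return A new `dq_generator_spec` whose marginals sum to `n`.
#' @export
scale_spec <- function(spec, n, modifier_rate = NULL,
                       stratifier_rate = NULL, seed = NULL) {
  total <- sum(spec$marginals$n)
  reps <- n %/% total
  rem <- n %% total
  base <- spec$marginals$n * reps
  if (rem > 0) {
    expanded <- rep(seq_len(nrow(spec$marginals)), spec$marginals$n)
    picked <- expanded[floor((seq_len(rem) - 1) * total / rem) + 1L]
    base <- base + tabulate(picked, nbins = nrow(spec$marginals))
  }
  marginals <- spec$marginals
  marginals$n <- as.integer(base)
  marginals <- filter(marginals, .data$n > 0)
  dq_generator_spec(
    marginals, network = spec$network,
    seed = seed %||% spec$seed,
    modifier_rate = modifier_rate %||% spec$modifier_rate,
    stratifier_rate = stratifier_rate %||% spec$stratifier_rate
  )
}

#' Read a generator spec from YAML
#'
#' Two layouts are accepted: `replica: OHDSI|CESR` (optionally with
#' `n_checks`, `modifier_rate`, `stratifier_rate`, `seed` overrides), or an
#' explicit `marginals:` list of `{de_term, de_domain, fn_term, fn_domain,
#' n, harmonization}` records with `network:`.
#'
#' @param path YAML file path.
#' @return A `dq_generator_spec`.
#' @export
read_generator_spec <- function(path) {
  if (!file.exists(path)) abort(sprintf("spec file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$replica)) {
    spec <- replica_spec(raw$replica, seed = raw$seed %||% 1L)
    if (!is.null(raw$n_checks) &&
        raw$n_checks != sum(spec$marginals$n)) {
      spec <- scale_spec(spec, raw$n_checks)
    }
    spec$modifier_rate <- raw$modifier_rate %||% spec$modifier_rate
    spec$stratifier_rate <- raw$stratifier_rate %||% spec$stratifier_rate
    return(spec)
  }
  if (is.null(raw$marginals)) {
    abort(sprintf("spec %s has neither `replica` nor `marginals`", path))
  }
  dq_generator_spec(
    yaml_tbl(raw$marginals), network = raw$network %||% "OTHER",
    seed = raw$seed %||% 1L, modifier_rate = raw$modifier_rate %||% 0,
    stratifier_rate = raw$stratifier_rate %||% 1
  )
}
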
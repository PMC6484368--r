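# Trainable extraction of the one data element and one function per check.
#
# The extractor is a dictionary NER with context-template backoff, which is
# sufficient for the highly structured narrative style of network DQ checks:
#
#   * a per-construct *term lexicon* of normalized surface terms observed in
#     gold annotations (longest match wins);
#   * per-construct *context templates* — the tokens flanking each gold span
#     (window configurable) with tokens that fall inside the other
#     construct's span generalized to a single-token wildcard `*` — which
#     recover terms never seen in training from their structural context;
#   * a *modifier stoplist* ("distinct", "unique", ...) whose tokens are
#     trimmed from the front of data-element candidates, so "distinct
#     persons" yields "persons".

BOUNDARY <- "<s>"
WILDCARD <- "*"

#' Default adjective-modifier stoplist
#'
#' Tokens trimmed from the front of data-element candidates found by context
#' templates, so that a modifier such as "distinct" is not mistaken for the
#' data element itself.
#'
#' @return Character vector of modifier tokens.
#' @export
default_stoplist <- function() c("distinct", "unique", "total")

#' Split a corpus into training and testing sets
#'
#' Reproducible random partition. The training-set size is
#' `round(train_fraction * n)` under the chosen rounding rule, with a
#' minimum of 1 and (for corpora of more than one check) a maximum of
#' `n - 1` so the test set is never empty.
#'
#' @param corpus Corpus tibble.
#' @param train_fraction Fraction in (0, 1) of checks assigned to training.
#' @param seed Integer seed; identical seeds give identical partitions.
#' @param round_mode `"nearest"` (ties rounded up, the default), `"up"`, or
#'   `"down"`. Exposed because published splits of real corpora are
#'   reported under more than one convention.
#' @return A list with corpus tibbles `train` and `test`.
#' @export
split_corpus <- function(corpus, train_fraction, seed,
                         round_mode = c("nearest", "up", "down")) {
  round_mode <- match.arg(round_mode)
  n <- nrow(corpus)
  if (n == 0) abort("cannot split an empty corpus")
  stopifnot(train_fraction > 0, train_fraction < 1)
  size <- switch(round_mode,
    nearest = floor(train_fraction * n + 0.5),
    up = ceiling(train_fraction * n),
    down = floor(train_fraction * n)
  )
  size <- max(1L, as.integer(size))
  if (n > 1L) size <- min(size, n - 1L)
  idx <- withr::with_seed(seed, sample.int(n, size))
  list(train = corpus[sort(idx), ], test = corpus[-sort(idx), ])
}

context_of <- function(tokens, from, to, other_lo, other_hi, window) {
  # match-form tokens at positions from..to, padded with the boundary
  # marker, with positions inside the other construct's span wildcarded
  pos <- seq(from, to)
  vapply(pos, function(p) {
    if (p < 1L || p > nrow(tokens)) return(BOUNDARY)
    if (!is.na(other_lo) && p >= other_lo && p <= other_hi) return(WILDCARD)
    tokens$match[p]
  }, character(1))
}

span_token_range <- function(tokens, start, end) {
  hit <- which(tokens$start < end & tokens$end > start)
  if (length(hit) == 0) c(NA_integer_, NA_integer_) else range(hit)
}

#' Train an extraction model from gold annotations
#'
#' Every annotated span contributes its normalized term to the construct's
#' lexicon and its flanking token context to the construct's template set.
#' Training has set semantics: duplicate annotations and their order do not
#' change the model.
#'
#' @param corpus Plain-text corpus tibble.
#' @param annotations Annotation tibble as returned by
#'   [parse_annotated_corpus()] (one row per check: spans + gold terms).
#' @param network Dialect tag of the model; defaults to the corpus network.
#' @param window Context-window width in tokens on each side (default 2).
#' @param stoplist Modifier stoplist (see [default_stoplist()]).
#' @return An object of class `dq_extraction_model`.
#' @export
train_extractor <- function(corpus, annotations, network = NULL,
                            window = 2L, stoplist = default_stoplist()) {
  if (is.null(annotations) || nrow(annotations) == 0) {
    abort("cannot train an extraction model from zero annotations")
  }
  network <- network %||% corpus$network[1]
  dat <- left_join(annotations, corpus, by = "check_id")
  if (any(is.na(dat$text))) {
    abort("annotations reference check_ids absent from the corpus")
  }
  lex <- list(); tpl <- list(); span_len <- 1L
  for (r in seq_len(nrow(dat))) {
    tokens <- tokenize_text(dat$text[r])
    de_rng <- span_token_range(tokens, dat$de_start[r], dat$de_end[r])
    fn_rng <- span_token_range(tokens, dat$fn_start[r], dat$fn_end[r])
    for (kind in construct_kinds()) {
      rng <- if (kind == "data_element") de_rng else fn_rng
      oth <- if (kind == "data_element") fn_rng else de_rng
      term <- if (kind == "data_element") dat$de_term[r] else dat$fn_term[r]
      lex[[length(lex) + 1L]] <- tibble(
        kind = kind, key = term_key(term), term = normalize_term(term)
      )
      span_len <- max(span_len, rng[2] - rng[1] + 1L)
      tpl[[length(tpl) + 1L]] <- tibble(
        kind = kind,
        left = paste(context_of(tokens, rng[1] - window, rng[1] - 1L,
                                oth[1], oth[2], window), collapse = " "),
        right = paste(context_of(tokens, rng[2] + 1L, rng[2] + window,
                                 oth[1], oth[2], window), collapse = " ")
      )
    }
  }
  model <- list(
    network = network,
    window = as.integer(window),
    max_span_tokens = span_len + 1L,
    lexicon = distinct(arrange(bind_rows(lex), .data$kind, .data$key)),
    templates = distinct(arrange(bind_rows(tpl), .data$kind, .data$left,
                                 .data$right)),
    stoplist = sort(unique(tolower(stoplist)))
  )
  structure(model, class = "dq_extraction_model")
}

#' @export
print.dq_extraction_model <- function(x, ...) {
  cat("<dq_extraction_model>", x$network, "\n")
  for (k in construct_kinds()) {
    cat(sprintf("  %s: %d lexicon terms, %d context templates\n", k,
                sum(x$lexicon$kind == k), sum(x$templates$kind == k)))
  }
  cat("  stoplist:", paste(x$stoplist, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize an extraction model to JSON
#'
#' Models are reload-identical: `read_extraction_model(write_extraction_model(m, p))`
#' equals `m`.
#'
#' @param model A `dq_extraction_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_extraction_model <- function(model, path) {
  jsonlite::write_json(
    list(
      format = "dqindexr-extraction-model", version = 1L,
      network = model$network, window = model$window,
      max_span_tokens = model$max_span_tokens,
      lexicon = model$lexicon, templates = model$templates,
      stoplist = model$stoplist
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read an extraction model from JSON
#'
#' @param path File written by [write_extraction_model()].
#' @return A `dq_extraction_model`.
#' @export
read_extraction_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(raw$format, "dqindexr-extraction-model")) {
    abort(sprintf("%s is not a dqindexr extraction model", path))
  }
  structure(
    list(
      network = raw$network, window = as.integer(raw$window),
      max_span_tokens = as.integer(raw$max_span_tokens),
      lexicon = as_tibble(raw$lexicon), templates = as_tibble(raw$templates),
      stoplist = as.character(raw$stoplist)
    ),
    class = "dq_extraction_model"
  )
}

match_context <- function(tokens, pattern, pos, other_range = NULL) {
  # pattern: match-form tokens / <s> / *, aligned with token positions
  # `pos` (possibly outside 1..n, where only <s> matches). A wildcard stands
  # for a token of the *other* construct's span: when that span is known it
  # must cover the wildcard's position, otherwise any real token matches.
  n <- nrow(tokens)
  all(vapply(seq_along(pattern), function(i) {
    p <- pattern[i]; at <- pos[i]
    if (at < 1L || at > n) return(p == BOUNDARY)
    if (p == WILDCARD) {
      if (is.null(other_range)) return(TRUE)
      return(at >= other_range[1] && at <= other_range[2])
    }
    if (p == BOUNDARY) return(FALSE)
    p == tokens$match[at]
  }, logical(1)))
}

candidate_tibble <- function(i, j) tibble(i = i, j = j)

lexicon_candidates <- function(tokens, keys, max_len) {
  n <- nrow(tokens)
  out <- list()
  for (i in seq_len(n)) {
    for (L in seq_len(min(max_len, n - i + 1L))) {
      key <- paste(tokens$match[i:(i + L - 1L)], collapse = " ")
      if (key %in% keys) out[[length(out) + 1L]] <- candidate_tibble(i, i + L - 1L)
    }
  }
  bind_rows(out)
}

template_candidates <- function(tokens, templates, max_len,
                                other_range = NULL) {
  n <- nrow(tokens)
  out <- list()
  for (t in seq_len(nrow(templates))) {
    left <- strsplit(templates$left[t], " ", fixed = TRUE)[[1]]
    right <- strsplit(templates$right[t], " ", fixed = TRUE)[[1]]
    # without the other span to pin its wildcards, a template needs at
    # least one concrete anchor token or it would match anywhere
    if (is.null(other_range) &&
        !any(!c(left, right) %in% c(BOUNDARY, WILDCARD))) {
      next
    }
    for (i in seq_len(n)) {
      for (L in seq_len(min(max_len, n - i + 1L))) {
        j <- i + L - 1L
        if (!match_context(tokens, left, seq(i - length(left), i - 1L),
                           other_range)) next
        if (!match_context(tokens, right, seq(j + 1L, j + length(right)),
                           other_range)) next
        out[[length(out) + 1L]] <- candidate_tibble(i, j)
      }
    }
  }
  bind_rows(out)
}

pick_winner <- function(text, tokens, cand) {
  # longest match (in characters), then leftmost
  cand <- mutate(cand,
    len = tokens$end[.data$j] - tokens$start[.data$i]
  ) |>
    arrange(desc(.data$len), .data$i)
  cand[1, ]
}

# Tokens that open a stratification or temporal clause ("by
# drug_concept_id", "across all years"). Such clauses are narrative
# qualifiers, never part of an extracted term, so template candidates are
# truncated at the first clause marker. Lexicon matches are exempt: a
# vocabulary term may legitimately contain these words ("paid by payer").
clause_markers <- function() c("by", "across")

truncate_at_clause <- function(cand, tokens) {
  for (r in seq_len(nrow(cand))) {
    span <- seq(cand$i[r], cand$j[r])
    hit <- span[tokens$match[span] %in% clause_markers()]
    if (length(hit)) cand$j[r] <- min(hit) - 1L
  }
  distinct(filter(cand, .data$i <= .data$j))
}

strip_modifiers <- function(cand, tokens, stoplist) {
  # stoplisted adjective modifiers at the front of a candidate belong to
  # the narrative, not to the data element
  for (r in seq_len(nrow(cand))) {
    while (cand$i[r] <= cand$j[r] &&
           tokens$match[cand$i[r]] %in% stoplist) {
      cand$i[r] <- cand$i[r] + 1L
    }
  }
  distinct(filter(cand, .data$i <= .data$j))
}

extract_one <- function(model, text) {
  tokens <- tokenize_text(text)
  winners <- stats::setNames(vector("list", 2), construct_kinds())
  # pass 1: longest lexicon match per construct
  for (kind in construct_kinds()) {
    keys <- model$lexicon$key[model$lexicon$kind == kind]
    cand <- lexicon_candidates(tokens, keys, model$max_span_tokens)
    if (nrow(cand) > 0) winners[[kind]] <- pick_winner(text, tokens, cand)
  }
  # pass 2 (twice, so a construct found by template can anchor the other):
  # context-template backoff for constructs without a lexicon match
  for (round in 1:2) {
    for (kind in construct_kinds()) {
      if (!is.null(winners[[kind]])) next
      other <- winners[[setdiff(construct_kinds(), kind)]]
      other_range <- if (!is.null(other)) c(other$i, other$j)
      tpl <- model$templates[model$templates$kind == kind, ]
      cand <- template_candidates(tokens, tpl, model$max_span_tokens,
                                  other_range)
      if (nrow(cand) > 0) cand <- truncate_at_clause(cand, tokens)
      if (kind == "data_element" && nrow(cand) > 0) {
        cand <- strip_modifiers(cand, tokens, model$stoplist)
      }
      if (nrow(cand) > 0) winners[[kind]] <- pick_winner(text, tokens, cand)
    }
  }
  purrr::map(winners, function(w) {
    if (is.null(w)) "" else token_span_surface(text, tokens, w$i, w$j)
  })
}

#' Extract the data element and function from each check
#'
#' Candidates are found per construct by longest lexicon match, falling back
#' to context-template matches; exactly one winner per construct is selected
#' (longest match, then leftmost). A check for which no candidate exists
#' yields a record with the `UNKNOWN` confidence flag — never an error.
#'
#' @param model A trained `dq_extraction_model`.
#' @param corpus Corpus tibble; its network must match the model's.
#' @return Tibble of extraction records, two rows (one per construct kind)
#'   per check: `check_id`, `kind`, `term`, `confidence_flag`.
#' @export
extract_constructs <- function(model, corpus) {
  if (!all(corpus$network == model$network)) {
    abort(sprintf("model is for network %s but the corpus contains other networks",
                  model$network))
  }
  purrr::list_rbind(purrr::map(seq_len(nrow(corpus)), function(r) {
    terms <- extract_one(model, corpus$text[r])
    bind_rows(
      extraction_record(corpus$check_id[r], "data_element",
                        terms$data_element),
      extraction_record(corpus$check_id[r], "function", terms[["function"]])
    )
  }))
}

#' Evaluate an extraction model against gold annotations
#'
#' A construct counts as correct iff the extracted term equals the gold
#' span's term after normalization (case fold + whitespace collapse,
#' punctuation preserved). The metric per construct is the proportion of
#' correctly identified constructs over the number of checks evaluated.
#'
#' @param model A `dq_extraction_model`.
#' @param corpus Plain-text corpus tibble.
#' @param annotations Gold annotation tibble (see
#'   [parse_annotated_corpus()]).
#' @return An object of class `dq_evaluation`: counts, per-construct
#'   proportions, and a `misses` tibble (check_id, kind, expected,
#'   produced) listing every miss for re-annotation.
#' @export
evaluate_extractor <- function(model, corpus, annotations) {
  if (nrow(annotations) == 0) abort("cannot evaluate against zero annotations")
  corpus <- corpus[corpus$check_id %in% annotations$check_id, ]
  got <- extract_constructs(model, corpus)
  gold <- tidyr::pivot_longer(
    annotations[c("check_id", "de_term", "fn_term")],
    -"check_id", names_to = "kind", values_to = "expected"
  ) |>
    mutate(kind = ifelse(.data$kind == "de_term", "data_element", "function"))
  cmp <- left_join(gold, got, by = c("check_id", "kind")) |>
    mutate(correct = normalize_term(.data$expected) == normalize_term(.data$term))
  n <- nrow(annotations)
  n_de <- sum(cmp$correct[cmp$kind == "data_element"])
  n_fn <- sum(cmp$correct[cmp$kind == "function"])
  structure(
    list(
      n_checks = n, n_correct_de = n_de, n_correct_fn = n_fn,
      proportion_de = n_de / n, proportion_fn = n_fn / n,
      misses = cmp |>
        filter(!.data$correct) |>
        select("check_id", "kind", expected = "expected", produced = "term")
    ),
    class = "dq_evaluation"
  )
}

#' @export
print.dq_evaluation <- function(x, ...) {
  cat(sprintf(
    "<dq_evaluation> %d checks | data elements %.1f%% | functions %.1f%% | %d miss(es)\n",
    x$n_checks, 100 * x$proportion_de, 100 * x$proportion_fn, nrow(x$misses)
  ))
  invisible(x)
}

#' @export
tidy.dq_evaluation <- function(x, ...) {
  tibble(
    kind = construct_kinds(),
    n_checks = x$n_checks,
    n_correct = c(x$n_correct_de, x$n_correct_fn),
    proportion = c(x$proportion_de, x$proportion_fn)
  )
}

#' Iterative annotate-train loop
#'
#' Reproduces the annotation protocol used to bootstrap extraction from a
#' small seed: start from a random initial subset of the annotated training
#' corpus, train, evaluate on the *full* training corpus, and — while either
#' construct's proportion correct is below `threshold` — add the annotations
#' of the missed checks to the subset and retrain. The annotated subset
#' grows strictly every iteration until convergence or exhaustion.
#'
#' @param corpus Plain-text training corpus tibble.
#' @param annotations Gold annotations for every check in `corpus`.
#' @param initial_subset_size Number of checks in the seed subset.
#' @param threshold Convergence threshold in (0, 1] for *each* construct's
#'   proportion correct (default 0.90).
#' @param max_iterations Iteration cap (default 10).
#' @param seed Integer seed for the initial subset draw.
#' @param window,stoplist Passed to [train_extractor()].
#' @return An object of class `dq_training_run`: `model`, `trace` (list of
#'   `dq_evaluation`, one per iteration), `converged`, `annotated_ids`. If
#'   the cap is exhausted below threshold a `dqindexr_nonconvergence`
#'   warning carrying the trace is signalled — never a silent success.
#' @export
iterative_train <- function(corpus, annotations, initial_subset_size,
                            threshold = 0.9, max_iterations = 10L, seed = 1L,
                            window = 2L, stoplist = default_stoplist()) {
  stopifnot(threshold > 0 || threshold == 0, threshold <= 1,
            initial_subset_size >= 1,
            initial_subset_size <= nrow(corpus))
  ids <- withr::with_seed(
    seed, sample(corpus$check_id, initial_subset_size)
  )
  ids <- sort(ids)
  trace <- list()
  converged <- FALSE
  model <- NULL
  for (it in seq_len(max_iterations)) {
    model <- train_extractor(
      corpus[corpus$check_id %in% ids, ],
      annotations[annotations$check_id %in% ids, ],
      network = corpus$network[1], window = window, stoplist = stoplist
    )
    report <- evaluate_extractor(model, corpus, annotations)
    trace[[it]] <- report
    if (min(report$proportion_de, report$proportion_fn) >= threshold) {
      converged <- TRUE
      break
    }
    new_ids <- setdiff(unique(report$misses$check_id), ids)
    if (length(new_ids) == 0) break  # nothing left to annotate
    ids <- sort(c(ids, new_ids))
  }
  if (!converged) {
    warning(warningCondition(
      sprintf(
        "iterative training did not reach the %.0f%% threshold within %d iteration(s); final proportions: DE %.1f%%, FN %.1f%%",
        100 * threshold, length(trace),
        100 * trace[[length(trace)]]$proportion_de,
        100 * trace[[length(trace)]]$proportion_fn
      ),
      class = "dqindexr_nonconvergence", trace = trace
    ))
  }
  structure(
    list(model = model, trace = trace, converged = converged,
         annotated_ids = ids, threshold = threshold, seed = seed),
    class = "dq_training_run"
  )
}

#' @export
print.dq_training_run <- function(x, ...) {
  cat(sprintf(
    "<dq_training_run> %d iteration(s), %s, %d annotated check(s)\n",
    length(x$trace), if (x$converged) "converged" else "NOT converged",
    length(x$annotated_ids)
  ))
  invisible(x)
}

#' @describeIn iterative_train One row per iteration: subset growth and
#'   per-construct proportions.
#' @param x A `dq_training_run`.
#' @param ... Unused.
#' @export
tidy.dq_training_run <- function(x, ...) {
  purrr::list_rbind(purrr::imap(x$trace, function(rep, it) {
    tibble(iteration = it, n_checks = rep$n_checks,
           proportion_de = rep$proportion_de,
           proportion_fn = rep$proportion_fn,
           n_misses = nrow(rep$misses))
  }))
}

#' @describeIn iterative_train One-row summary of the run.
#' @export
glance.dq_training_run <- function(x, ...) {
  final <- x$trace[[length(x$trace)]]
  tibble(
    iterations = length(x$trace), converged = x$converged,
    n_annotated = length(x$annotated_ids),
    proportion_de = final$proportion_de,
    proportion_fn = final$proportion_fn
  )
}
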
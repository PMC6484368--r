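# Staged workflow orchestration: simulate -> train -> extract ->
# categorize -> report. Each stage writes flat-file artifacts plus a JSON
# manifest (inputs, config hash, counts) into one output directory, and a
# rerun with identical inputs and seed produces identical manifests. A thin
# command-line wrapper over these functions ships in inst/cli/dqindex.R.

#' Assemble a run configuration
#'
#' Defaults follow the reference protocol: 10% training fraction, 90%
#' convergence threshold per construct, at most 10 iterations. Precedence
#' when loading from file is overrides > file > defaults.
#'
#' @param ... Named overrides of the defaults.
#' @param file Optional YAML file of settings.
#' @return Named list of class `dq_config`.
#' @export
dq_config <- function(..., file = NULL) {
  defaults <- list(
    train_fraction = 0.10, threshold = 0.90, max_iterations = 10L,
    seed = 1L, window = 2L, stoplist = default_stoplist(),
    fallback = FALSE, heatmap = FALSE, round_mode = "nearest"
  )
  from_file <- if (!is.null(file)) yaml::read_yaml(file) else list()
  overrides <- list(...)
  cfg <- utils::modifyList(utils::modifyList(defaults, from_file), overrides)
  structure(cfg, class = c("dq_config", "list"))
}

config_hash <- function(cfg) rlang::hash(unclass(cfg))

stage_path <- function(out_dir, name) file.path(out_dir, name)

write_manifest <- function(out_dir, stage, cfg, inputs, counts) {
  jsonlite::write_json(
    list(stage = stage, config_hash = config_hash(cfg), inputs = inputs,
         counts = counts),
    stage_path(out_dir, sprintf("manifest_%s.json", stage)),
    auto_unbox = TRUE, digits = NA
  )
}

require_artifact <- function(path, produced_by) {
  if (!file.exists(path)) {
    abort(sprintf("missing artifact %s; run %s first", path, produced_by))
  }
  path
}

network_taxonomy <- function(network, out_dir = NULL) {
  switch(network,
    OHDSI = ohdsi_taxonomy(),
    CESR = {
      lex_path <- if (!is.null(out_dir)) {
        stage_path(out_dir, "cesr_lexicon.csv")
      }
      lex <- if (!is.null(lex_path) && file.exists(lex_path)) {
        readr::read_csv(lex_path, col_types = readr::cols(.default = "c"),
                        na = character())
      }
      cesr_taxonomy(de_lexicon = lex)
    },
    abort(sprintf("no packaged taxonomy for network %s", network))
  )
}

#' Run the simulate stage
#'
#' Generates a gold-annotated corpus from a generator spec and writes
#' `corpus_annotated.csv`, `corpus.csv`, `gold_annotations.csv`,
#' `gold_indexed.csv` (and, for CESR, the synthesized lexicon
#' `cesr_lexicon.csv`) into `out_dir`.
#'
#' @param spec A `dq_generator_spec` or path to a spec YAML.
#' @param out_dir Output directory (created if needed).
#' @param config A [dq_config()].
#' @return The `dq_synthetic_corpus`, invisibly.
#' @export
dq_run_simulate <- function(spec, out_dir, config = dq_config()) {
  if (is.character(spec)) spec <- read_generator_spec(spec)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_corpus(spec)
  write_corpus(gen$annotated, stage_path(out_dir, "corpus_annotated.csv"))
  write_corpus(gen$corpus, stage_path(out_dir, "corpus.csv"))
  readr::write_csv(gen$annotations,
                   stage_path(out_dir, "gold_annotations.csv"), na = "")
  write_indexed_checks(gen$indexed, stage_path(out_dir, "gold_indexed.csv"))
  if (identical(spec$network, "CESR")) {
    readr::write_csv(generate_cesr_lexicon(),
                     stage_path(out_dir, "cesr_lexicon.csv"), na = "")
  }
  write_manifest(out_dir, "simulate", config,
                 inputs = list(network = spec$network, seed = spec$seed,
                               modifier_rate = spec$modifier_rate),
                 counts = list(n_checks = nrow(gen$corpus)))
  invisible(gen)
}

read_stage_corpus <- function(out_dir, annotated = FALSE) {
  file <- if (annotated) "corpus_annotated.csv" else "corpus.csv"
  path <- require_artifact(stage_path(out_dir, file), "dq_run_simulate")
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = character())
  harm <- raw$harmonization
  harm[harm == ""] <- NA_character_
  dq_corpus(raw$check_text, network = raw$network, check_id = raw$check_id,
            harmonization = harm)
}

#' Run the train stage
#'
#' Trains the extractor on the annotated corpus with the iterative
#' annotate-train loop and writes `model.json` plus the per-iteration
#' `training_trace.csv`.
#'
#' @param out_dir Directory holding the simulate-stage artifacts.
#' @param config A [dq_config()].
#' @return The `dq_training_run`, invisibly.
#' @export
dq_run_train <- function(out_dir, config = dq_config()) {
  annotated <- read_stage_corpus(out_dir, annotated = TRUE)
  parsed <- parse_annotated_corpus(annotated)
  n0 <- max(1L, floor(config$train_fraction * nrow(annotated) + 0.5))
  run <- iterative_train(
    parsed$corpus, parsed$annotations, initial_subset_size = n0,
    threshold = config$threshold, max_iterations = config$max_iterations,
    seed = config$seed, window = config$window, stoplist = config$stoplist
  )
  write_extraction_model(run$model, stage_path(out_dir, "model.json"))
  readr::write_csv(tidy(run), stage_path(out_dir, "training_trace.csv"))
  write_manifest(out_dir, "train", config,
                 inputs = list(corpus = "corpus_annotated.csv"),
                 counts = list(iterations = length(run$trace),
                               converged = run$converged,
                               n_annotated = length(run$annotated_ids)))
  invisible(run)
}

#' Run the extract stage
#'
#' Applies the trained model to the plain corpus and writes
#' `extractions.csv` (one row per construct per check).
#'
#' @inheritParams dq_run_train
#' @return The extraction-record tibble, invisibly.
#' @export
dq_run_extract <- function(out_dir, config = dq_config()) {
  model <- read_extraction_model(
    require_artifact(stage_path(out_dir, "model.json"), "dq_run_train")
  )
  corpus <- read_stage_corpus(out_dir)
  recs <- extract_constructs(model, corpus)
  readr::write_csv(recs, stage_path(out_dir, "extractions.csv"))
  write_manifest(out_dir, "extract", config,
                 inputs = list(model = "model.json", corpus = "corpus.csv"),
                 counts = list(
                   n_checks = nrow(corpus),
                   n_unknown = sum(recs$confidence_flag == "UNKNOWN")
                 ))
  invisible(recs)
}

#' Run the categorize stage
#'
#' Maps extracted terms to taxonomy domains and writes `indexed.csv` plus
#' `unmapped_terms.csv` (the manual-review surface).
#'
#' @inheritParams dq_run_train
#' @return The indexed-check tibble, invisibly.
#' @export
dq_run_categorize <- function(out_dir, config = dq_config()) {
  recs <- readr::read_csv(
    require_artifact(stage_path(out_dir, "extractions.csv"),
                     "dq_run_extract"),
    col_types = readr::cols(.default = "c"), na = character()
  )
  corpus <- read_stage_corpus(out_dir)
  tax <- network_taxonomy(corpus$network[1], out_dir)
  indexed <- index_checks(corpus, recs, tax, fallback = config$fallback)
  write_indexed_checks(indexed, stage_path(out_dir, "indexed.csv"))
  unmapped <- indexed |>
    filter(.data$de_domain == uncategorized() |
             .data$fn_domain == uncategorized())
  readr::write_csv(unmapped, stage_path(out_dir, "unmapped_terms.csv"),
                   na = "")
  write_manifest(out_dir, "categorize", config,
                 inputs = list(extractions = "extractions.csv"),
                 counts = list(n_checks = nrow(indexed),
                               n_unmapped = nrow(unmapped)))
  invisible(indexed)
}

#' Run the report stage
#'
#' Writes the descriptive outputs: `frequency_data_element.csv`,
#' `frequency_function.csv`, `pairing_matrix.csv`,
#' `harmonization_crosstab.csv`, a JSON `summary.json`, and optionally a
#' PNG heat map.
#'
#' @inheritParams dq_run_train
#' @return Named list of the report objects, invisibly.
#' @export
dq_run_report <- function(out_dir, config = dq_config()) {
  indexed <- read_indexed_checks(
    require_artifact(stage_path(out_dir, "indexed.csv"), "dq_run_categorize")
  )
  freq_de <- dq_frequency_table(indexed, "data_element")
  freq_fn <- dq_frequency_table(indexed, "function")
  pairing <- dq_pairing_matrix(indexed)
  crosstab <- dq_harmonization_crosstab(indexed, "data_element")
  readr::write_csv(freq_de, stage_path(out_dir, "frequency_data_element.csv"))
  readr::write_csv(freq_fn, stage_path(out_dir, "frequency_function.csv"))
  write_pairing_matrix(pairing, stage_path(out_dir, "pairing_matrix.csv"))
  readr::write_csv(crosstab$cells,
                   stage_path(out_dir, "harmonization_crosstab.csv"))
  if (isTRUE(config$heatmap)) {
    ggplot2::ggsave(stage_path(out_dir, "pairing_heatmap.png"),
                    autoplot(pairing), width = 8, height = 6, dpi = 150)
  }
  jsonlite::write_json(
    list(
      n_checks = pairing$n_total,
      top_pair = glance(pairing)$top_pair,
      top_pair_n = glance(pairing)$top_pair_n,
      n_uncategorized = pairing$n_uncategorized,
      n_unlabeled = sum(crosstab$unlabeled$n)
    ),
    stage_path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA
  )
  write_manifest(out_dir, "report", config,
                 inputs = list(indexed = "indexed.csv"),
                 counts = list(n_checks = pairing$n_total))
  invisible(list(frequency_de = freq_de, frequency_fn = freq_fn,
                 pairing = pairing, crosstab = crosstab))
}

#' Run the full pipeline
#'
#' simulate -> train -> extract -> categorize -> report, in one call.
#'
#' @inheritParams dq_run_simulate
#' @return The report list, invisibly.
#' @export
dq_run_pipeline <- function(spec, out_dir, config = dq_config()) {
  dq_run_simulate(spec, out_dir, config)
  dq_run_train(out_dir, config)
  dq_run_extract(out_dir, config)
  dq_run_categorize(out_dir, config)
  dq_run_report(out_dir, config)
}
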
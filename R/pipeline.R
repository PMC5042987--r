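#' Assemble a pipeline run configuration
#'
#' Bundles and validates everything a full analysis needs: the corpus
#' location, the temporal discretization, the preprocessing choices, the
#' HDP hyperparameters, and the single graph operating point `zeta`.
#'
#' @param input Path to the corpus (JSONL or CSV; see [read_corpus()]).
#' @param out_dir Output directory for the result bundle.
#' @param epoch_length Epoch duration in days.
#' @param overlap Epoch overlap in days (default 0).
#' @param format Corpus format, `"auto"`, `"jsonl"` or `"csv"`.
#' @param energy Vocabulary energy fraction in `(0, 1]` (default 0.9).
#' @param stopwords Path to a stop-word file, or `NULL` for the built-in
#'   list.
#' @param lemmatizer Path to a two-column CSV (`term`, `lemma`), or `NULL`
#'   for no lemmatization.
#' @param control HDP hyperparameters, an [hdp_control()].
#' @param zeta CDF operating point in `[0, 1]` (default 0.9).
#' @param seed Master seed; all per-epoch fits derive their seeds from it.
#' @return A list of class `tf_run_config`.
#' @export
run_config <- function(input, out_dir, epoch_length, overlap = 0,
                       format = "auto", energy = 0.9, stopwords = NULL,
                       lemmatizer = NULL, control = hdp_control(),
                       zeta = 0.9, seed = 1L) {
  if (!isTRUE(zeta >= 0 && zeta <= 1)) abort("`zeta` must be in [0, 1].")
  if (!isTRUE(energy > 0 && energy <= 1)) abort("`energy` must be in (0, 1].")
  if (!isTRUE(epoch_length > 0)) abort("`epoch_length` must be positive.")
  if (overlap < 0 || overlap >= epoch_length) {
    abort("`overlap` must satisfy 0 <= overlap < epoch_length.")
  }
  stopifnot(inherits(control, "hdp_control"))
  for (p in c(input, stopwords, lemmatizer)) {
    if (!is.null(p) && !file.exists(p)) abort(sprintf("Path does not exist: %s", p))
  }
  structure(
    list(input = input, format = format, out_dir = out_dir,
         epoch_length = epoch_length, overlap = overlap,
         energy = energy, stopwords = stopwords, lemmatizer = lemmatizer,
         control = control, zeta = zeta, seed = as.integer(seed)),
    class = "tf_run_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; HDP hyperparameters go
#' under an `hdp:` section with the argument names of [hdp_control()].
#'
#' @param path YAML file path.
#' @param ... Overrides applied on top of the file's values (flags beat
#'   file values).
#' @return A `tf_run_config`.
#' @export
read_run_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  hdp <- do.call(hdp_control, raw$hdp %||% list())
  raw$hdp <- NULL
  args <- utils::modifyList(c(raw, list(control = hdp)), list(...))
  do.call(run_config, args)
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full temporal topic evolution pipeline
#'
#' Executes read, preprocess, epoch partition, per-epoch HDP fitting, the
#' three relatedness graphs (BHD, forward KLD, backward KLD), CDF pruning
#' at `zeta`, event classification and export. The output bundle contains
#' the epoch assignment table, vocabulary, per-epoch topic CSVs, one
#' GraphML and one JSON file per pruned graph, the event table, and a
#' manifest recording the configuration, seed and package version.
#' Identical configuration and seed reproduce identical outputs; on
#' failure, partial outputs are removed.
#'
#' @param config A [run_config()] (or path to a YAML file for
#'   [read_run_config()]).
#' @return Invisibly, a list with the in-memory results: `docs`, `epochs`,
#'   `vocab`, `topic_sets`, `graphs` (full), `pruned` (at `zeta`),
#'   `events`, and `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "tf_run_config"))

  created <- !dir.exists(config$out_dir)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ok <- FALSE
  on.exit({
    if (!ok) {
      unlink(if (created) config$out_dir else
               list.files(config$out_dir, full.names = TRUE), recursive = TRUE)
    }
  }, add = TRUE)

  stops <- if (is.null(config$stopwords)) default_stopwords()
           else read_stopwords(config$stopwords)
  lemma <- NULL
  if (!is.null(config$lemmatizer)) {
    lt <- readr::read_csv(config$lemmatizer,
                          col_types = readr::cols(.default = readr::col_character()))
    lemma <- setNames(lt$lemma, lt$term)
  }

  docs <- pipeline_stage("read", read_corpus(config$input, config$format))
  docs <- pipeline_stage("preprocess", tokenize_corpus(docs, lemma, stops))
  epochs <- pipeline_stage("partition",
                           partition_epochs(docs, config$epoch_length, config$overlap))
  vocab <- pipeline_stage("vocabulary",
                          select_vocabulary(corpus_term_counts(docs), config$energy))
  counts <- pipeline_stage("encode", encode_corpus(docs, vocab))
  message(sprintf("topicflow: %d docs, %d epochs, vocabulary %d terms, %d tokens in vocabulary",
                  nrow(docs), nrow(epochs$epochs), length(vocab), sum(counts)))

  topic_sets <- pipeline_stage("fit",
                               fit_all_epochs(counts, epochs, config$control, config$seed))
  message(sprintf("topicflow: topics per epoch: %s",
                  paste(vapply(topic_sets, function(s) nrow(s$phi), integer(1)),
                        collapse = ", ")))

  metrics <- c("bhd", "kld_forward", "kld_backward")
  graphs <- pipeline_stage("graph",
                           setNames(purrr::map(metrics, ~build_full_graph(topic_sets, .x)), metrics))
  pruned <- pipeline_stage("prune",
                           purrr::map(graphs, prune_graph, zeta = config$zeta))
  events <- pipeline_stage("events",
                           classify_events(pruned$bhd, pruned$kld_forward, pruned$kld_backward))

  pipeline_stage("export", {
    write_epoch_assignment(epochs, file.path(config$out_dir, "epochs.csv"))
    write_vocabulary(vocab, file.path(config$out_dir, "vocabulary.txt"))
    write_topic_sets(topic_sets, file.path(config$out_dir, "topics"))
    for (m in metrics) {
      write_graphml(pruned[[m]], file.path(config$out_dir, sprintf("graph_%s.graphml", m)))
      write_graph_json(pruned[[m]], file.path(config$out_dir, sprintf("graph_%s.json", m)),
                       topic_sets = topic_sets)
    }
    write_events(events, file.path(config$out_dir, "events.csv"))
    manifest <- list(
      package = "topicflow",
      version = as.character(utils::packageVersion("topicflow")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = config$seed,
      zeta = config$zeta,
      energy = config$energy,
      epoch_length = config$epoch_length,
      overlap = config$overlap,
      input = config$input,
      hdp = unclass(config$control)
    )
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  ok <- TRUE
  invisible(list(docs = docs, epochs = epochs, vocab = vocab,
                 topic_sets = topic_sets, graphs = graphs, pruned = pruned,
                 events = events, out_dir = config$out_dir))
}
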
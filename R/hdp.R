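#' Hyperparameters for the epoch-wise HDP topic model
#'
#' The model places a corpus-level Dirichlet process DP(`gamma`, H) over
#' topics, where the base measure H is a symmetric Dirichlet(`eta`) over
#' the vocabulary, and a document-level DP(`alpha0`, G0) whose base measure
#' G0 is drawn from the corpus-level DP. Every epoch is fitted with the
#' same hyperparameters and the same base measure, which is what makes
#' topic distributions across epochs comparable; atoms themselves are not
#' shared across epochs (cross-epoch linkage is exactly what the temporal
#' relatedness graph provides).
#'
#' @param gamma Corpus-level DP concentration (> 0). Larger values admit
#'   more topics per epoch.
#' @param alpha0 Document-level DP concentration (> 0); governs how many
#'   topics a single document mixes.
#' @param eta Symmetric Dirichlet parameter of the base measure over the
#'   vocabulary (> 0). Small values (default 0.01) favour sparse,
#'   well-separated topics.
#' @param max_iters Total Gibbs sweeps; the returned state is the final
#'   sweep.
#' @param burn_in Sweeps regarded as burn-in (`burn_in < max_iters`); used
#'   by convergence diagnostics.
#' @param sample_concentration If `TRUE`, resample `gamma` and `alpha0`
#'   each sweep under vague Gamma(1, 1) priors. Off by default.
#' @param min_topic_tokens Topics holding fewer tokens than this in the
#'   final state are dropped from the topic set (default 1, i.e. only
#'   empty topics go), avoiding spurious singleton nodes in the graph.
#' @return A list of class `hdp_control`.
#' @export
hdp_control <- function(gamma = 1.0, alpha0 = 1.0, eta = 0.01,
                        max_iters = 1000L, burn_in = 500L,
                        sample_concentration = FALSE,
                        min_topic_tokens = 1L) {
  stopifnot(gamma > 0, alpha0 > 0, eta > 0)
  max_iters <- as.integer(max_iters)
  burn_in <- as.integer(burn_in)
  if (!(burn_in < max_iters) || max_iters < 1L || burn_in < 0L) {
    abort("Need 0 <= burn_in < max_iters.")
  }
  structure(
    list(gamma = gamma, alpha0 = alpha0, eta = eta,
         max_iters = max_iters, burn_in = burn_in,
         sample_concentration = isTRUE(sample_concentration),
         min_topic_tokens = as.integer(min_topic_tokens)),
    class = "hdp_control"
  )
}

#' Fit one epoch's topics with the HDP Gibbs sampler
#'
#' Runs the direct-assignment Gibbs sampler on the epoch's document-term
#' counts and returns the assignment state at the final sweep. Identical
#' `seed` and input give an identical state.
#'
#' @param counts Sparse or dense document-term count matrix for the epoch
#'   (documents as rows, vocabulary terms as columns).
#' @param control An [hdp_control()] object.
#' @param seed Integer RNG seed for this fit.
#' @param epoch Epoch index recorded on the result (default 1).
#' @param heldout Optional held-out document-term count matrix over the
#'   same vocabulary; if given, a per-sweep held-out predictive
#'   log-likelihood trace is recorded for convergence diagnostics.
#' @return An object of class `tf_hdp`: count statistics (`n_kw`, `n_k`,
#'   `n_dk`), the global stick `beta`, the token assignments `z`, the
#'   number of active topics `K`, diagnostic traces, and the control used.
#' @export
fit_epoch_hdp <- function(counts, control = hdp_control(), seed = 1L,
                          epoch = 1L, heldout = NULL) {
  stopifnot(inherits(control, "hdp_control"))
  counts <- as_count_matrix(counts)
  tok <- expand_tokens(counts)
  if (length(tok$word) == 0L) {
    abort(sprintf(
      "Epoch %d has no documents with in-vocabulary tokens; widen the epochs or lower the vocabulary energy.",
      epoch))
  }
  hw <- integer(0)
  if (!is.null(heldout)) {
    heldout <- as_count_matrix(heldout)
    if (ncol(heldout) != ncol(counts)) abort("`heldout` must share the epoch vocabulary.")
    hw <- expand_tokens(heldout)$word
  }
  set.seed(as.integer(seed))
  fit <- .hdp_gibbs_cpp(tok$doc, tok$word, nrow(counts), ncol(counts),
                        control$gamma, control$alpha0, control$eta,
                        control$max_iters, control$sample_concentration, hw)
  dimnames(fit$n_kw) <- list(NULL, colnames(counts))
  structure(
    c(fit,
      list(epoch = as.integer(epoch), seed = as.integer(seed),
           vocab = colnames(counts), doc_ids = rownames(counts),
           n_tokens = length(tok$word), control = control)),
    class = "tf_hdp"
  )
}

# expand a count matrix into one entry per token instance, row-major
# within document, words in column order: deterministic
expand_tokens <- function(counts) {
  tm <- Matrix::t(counts)               # column-oriented access per document
  ptr <- tm@p
  words <- tm@i                         # 0-based term indices
  reps <- tm@x
  doc <- rep.int(rep(seq_len(ncol(tm)) - 1L, times = diff(ptr)), as.integer(reps))
  word <- rep.int(words, as.integer(reps))
  list(doc = as.integer(doc), word = as.integer(word))
}

as_count_matrix <- function(counts) {
  m <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"), "generalMatrix")
  if (any(m@x < 0) || any(m@x != round(m@x))) abort("Counts must be non-negative integers.")
  m
}

#' @export
print.tf_hdp <- function(x, ...) {
  cat(sprintf("<tf_hdp> epoch %d: %d topics, %d docs, %d tokens (%d sweeps, seed %d)\n",
              x$epoch, x$K, nrow(x$n_dk), x$n_tokens, x$control$max_iters, x$seed))
  invisible(x)
}

#' @export
glance.tf_hdp <- function(x, ...) {
  tibble(epoch = x$epoch, n_topics = x$K, n_docs = nrow(x$n_dk),
         n_tokens = x$n_tokens, sweeps = x$control$max_iters,
         gamma = x$gamma, alpha0 = x$alpha0, seed = x$seed)
}

#' Smoothed point estimate of an epoch's topics
#'
#' Converts a fitted sampler state into a [topic_set()]: the posterior-mean
#' topic-term distributions under the Dirichlet(`eta`) base measure,
#' \eqn{\phi_{kw} = (n_{kw} + \eta) / (n_k + V\eta)}, with popularity
#' weights \eqn{\pi_k = n_k / \sum_j n_j}. Smoothing makes every
#' distribution strictly positive, so all downstream relatedness weights
#' are finite. Topics below the control's `min_topic_tokens` are dropped
#' and the popularity weights renormalized.
#'
#' @param state A `tf_hdp` fit.
#' @param control Hyperparameters; defaults to those recorded in `state`.
#' @return A `tf_topics` topic set for the state's epoch.
#' @export
estimate_topics <- function(state, control = state$control) {
  stopifnot(inherits(state, "tf_hdp"))
  keep <- which(state$n_k >= max(control$min_topic_tokens, 1L))
  if (length(keep) == 0L) abort("No topic reaches `min_topic_tokens`.")
  eta <- control$eta
  nkw <- state$n_kw[keep, , drop = FALSE]
  nk <- state$n_k[keep]
  phi <- (nkw + eta) / (nk + ncol(nkw) * eta)
  topic_set(phi, weights = nk / sum(nk), epoch = state$epoch,
            vocab = state$vocab)
}

#' Fit every epoch of an encoded corpus
#'
#' Fits one HDP per epoch, all sharing the same hyperparameters and
#' Dirichlet base measure, and returns the per-epoch topic sets in epoch
#' order. Per-epoch seeds are derived deterministically from `seed`, so a
#' master seed fixes the whole analysis.
#'
#' @param counts Document-term count matrix for the full corpus (rows
#'   named by `doc_id`).
#' @param epochs A `tf_epochs` partition of the same documents.
#' @param control An [hdp_control()].
#' @param seed Master integer seed.
#' @return A list of `tf_topics`, one per epoch, with class
#'   `tf_topic_sets`; fitted `tf_hdp` states attached as attribute
#'   `"fits"`.
#' @export
fit_all_epochs <- function(counts, epochs, control = hdp_control(), seed = 1L) {
  stopifnot(inherits(epochs, "tf_epochs"))
  counts <- as_count_matrix(counts)
  if (is.null(rownames(counts))) abort("`counts` must have doc_id rownames.")
  set.seed(as.integer(seed))
  epoch_ids <- epochs$epochs$epoch
  seeds <- sample.int(.Machine$integer.max - 1L, length(epoch_ids))
  fits <- vector("list", length(epoch_ids))
  sets <- vector("list", length(epoch_ids))
  for (i in seq_along(epoch_ids)) {
    t <- epoch_ids[i]
    ids <- epochs$assignment$doc_id[epochs$assignment$epoch == t]
    rows <- intersect(rownames(counts), ids)
    sub <- counts[rows, , drop = FALSE]
    fits[[i]] <- tryCatch(
      fit_epoch_hdp(sub, control = control, seed = seeds[i], epoch = t),
      error = function(e) abort(sprintf("Epoch %d: %s", t, conditionMessage(e)))
    )
    sets[[i]] <- estimate_topics(fits[[i]], control)
  }
  structure(sets, class = "tf_topic_sets", fits = fits, seed = as.integer(seed))
}

#' @export
print.tf_topic_sets <- function(x, ...) {
  cat(sprintf("<tf_topic_sets> %d epochs; topics per epoch: %s\n",
              length(x), paste(vapply(x, function(s) nrow(s$phi), integer(1)),
                               collapse = ", ")))
  invisible(x)
}

#' @export
tidy.tf_topic_sets <- function(x, ...) {
  purrr::map_dfr(x, tidy, ...)
}

#' Export per-epoch topic sets as CSV
#'
#' Writes one matrix CSV per epoch (rows = topics, columns = vocabulary
#' terms) plus a sidecar CSV of `(epoch, topic_id, popularity, n_topics)`.
#'
#' @param topic_sets A `tf_topic_sets` list.
#' @param dir Output directory (created if absent).
#' @return The sidecar path, invisibly.
#' @export
write_topic_sets <- function(topic_sets, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  side <- purrr::map_dfr(topic_sets, function(s) {
    path <- file.path(dir, sprintf("topics_epoch%03d.csv", s$epoch))
    readr::write_csv(as_tibble(s$phi, rownames = "topic_id"), path)
    tibble(epoch = s$epoch, topic_id = rownames(s$phi),
           popularity = unname(s$weights), n_topics = nrow(s$phi))
  })
  side_path <- file.path(dir, "topic_summary.csv")
  readr::write_csv(side, side_path)
  invisible(side_path)
}
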
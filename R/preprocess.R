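#' Normalize raw text into a token stream
#'
#' Lower-cases, tokenizes on non-alphabetic characters, drops tokens
#' shorter than two letters, applies a pluggable lemmatizer and removes
#' stop-words, preserving token order. Lemmatization is deliberately
#' "soft" (a term-to-term lookup with identity fallback) and no stemming
#' is performed: heuristic stemming rules routinely distort meaning in
#' technical vocabulary, which matters when topics are read by domain
#' experts.
#'
#' @param text A character string (one document).
#' @param lemmatizer Either a named character vector mapping terms to their
#'   lemmas, or a function taking and returning a character vector of
#'   tokens. Unmapped terms pass through unchanged.
#' @param stopwords Character vector of stop-words to remove (applied after
#'   lemmatization). See [default_stopwords()].
#' @return Character vector of normalized tokens (possibly empty).
#' @examples
#' normalize_tokens("Autism spectrum disorders are",
#'                  lemmatizer = c(disorders = "disorder"),
#'                  stopwords = "are")
#' @export
normalize_tokens <- function(text, lemmatizer = NULL, stopwords = character()) {
  if (length(text) != 1L || is.na(text)) abort("`text` must be a single string.")
  toks <- stringr::str_split_1(stringr::str_to_lower(text), "[^a-z]+")
  toks <- toks[nchar(toks) >= 2L]
  if (length(toks) == 0L) return(character())
  if (!is.null(lemmatizer)) {
    if (is.function(lemmatizer)) {
      toks <- lemmatizer(toks)
    } else {
      hit <- toks %in% names(lemmatizer)
      toks[hit] <- unname(lemmatizer[toks[hit]])
    }
  }
  toks[!toks %in% stopwords]
}

#' Built-in English stop-word list
#'
#' A small general-purpose list shipped with the package, read from
#' `extdata/stopwords.txt` (one term per line). Users with
#' domain-specific needs should supply their own via [read_stopwords()].
#'
#' @return Character vector of stop-words.
#' @export
default_stopwords <- function() {
  read_stopwords(system.file("extdata", "stopwords.txt", package = "topicflow"))
}

#' Read a stop-word list (one term per line)
#'
#' @param path Path to a plain-text file.
#' @return Character vector.
#' @export
read_stopwords <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x[nzchar(x)]
}

#' Select a vocabulary by the cumulative-energy criterion
#'
#' Keeps the smallest frequency-ranked prefix of terms whose summed counts
#' reach at least `energy` times the total token count ("the terms
#' explaining 90% of the energy", with energy read as cumulative
#' term-frequency mass). Terms are ranked by descending count with ties
#' broken lexicographically; if the cut falls inside a tie group, every
#' term at the admitted frequency is included, so the result does not
#' depend on arbitrary ordering within ties.
#'
#' @param term_counts Named numeric vector of positive term counts.
#' @param energy Fraction of total token mass to retain, in `(0, 1]`.
#' @return A character vector of terms in rank order, classed `tf_vocab`,
#'   with attributes `energy` (the requested fraction) and `coverage` (the
#'   fraction actually covered).
#' @export
select_vocabulary <- function(term_counts, energy = 0.9) {
  if (length(term_counts) == 0L) abort("`term_counts` is empty.")
  if (is.null(names(term_counts)) || any(!nzchar(names(term_counts)))) {
    abort("`term_counts` must be named by term.")
  }
  if (any(term_counts <= 0)) abort("All term counts must be positive.")
  if (!isTRUE(energy > 0 && energy <= 1)) abort("`energy` must be in (0, 1].")
  ord <- order(-term_counts, names(term_counts))
  counts <- term_counts[ord]
  cum <- cumsum(counts)
  total <- sum(counts)
  cut <- which(cum >= energy * total)[1L]
  # pull in every term tied at the frequency admitted at the cut
  cut_freq <- counts[cut]
  cut <- max(which(counts == cut_freq))
  vocab <- names(counts)[seq_len(cut)]
  structure(vocab, class = "tf_vocab",
            energy = energy, coverage = unname(cum[cut] / total))
}

#' @export
print.tf_vocab <- function(x, ...) {
  cat(sprintf("<tf_vocab> %d terms covering %.1f%% of token mass (requested %.0f%%)\n",
              length(x), 100 * attr(x, "coverage"), 100 * attr(x, "energy")))
  invisible(x)
}

#' Write / read a vocabulary (one term per line, rank order)
#'
#' @param vocab A `tf_vocab` or character vector.
#' @param path File path.
#' @return `path` (write) or a character vector (read), invisibly for write.
#' @export
write_vocabulary <- function(vocab, path) {
  writeLines(as.character(vocab), path)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  readLines(path, warn = FALSE)
}

#' Tokenize a whole corpus
#'
#' Applies [normalize_tokens()] to every document, adding a `tokens`
#' list-column.
#'
#' @param docs Corpus tibble with a `text` column.
#' @inheritParams normalize_tokens
#' @return `docs` with a `tokens` list-column appended.
#' @export
tokenize_corpus <- function(docs, lemmatizer = NULL, stopwords = default_stopwords()) {
  docs$tokens <- purrr::map(docs$text, normalize_tokens,
                            lemmatizer = lemmatizer, stopwords = stopwords)
  docs
}

#' Count term occurrences across a tokenized corpus
#'
#' @param docs Tibble with a `tokens` list-column.
#' @return Named integer vector of corpus-level term counts.
#' @export
corpus_term_counts <- function(docs) {
  tab <- table(unlist(docs$tokens))
  setNames(as.integer(tab), names(tab))
}

#' Encode tokenized documents as a sparse document-term count matrix
#'
#' Out-of-vocabulary tokens are dropped; each row's total equals the
#' number of the document's retained (in-vocabulary) tokens.
#'
#' @param docs Tibble with `doc_id` and a `tokens` list-column.
#' @param vocab Vocabulary (character vector / `tf_vocab`).
#' @return A `Matrix::dgCMatrix` of non-negative integer counts with
#'   documents as rows (named by `doc_id`) and vocabulary terms as columns.
#' @export
encode_corpus <- function(docs, vocab) {
  vocab <- as.character(vocab)
  if (length(vocab) == 0L) abort("`vocab` must be non-empty.")
  n <- nrow(docs)
  triplets <- purrr::map_dfr(seq_len(n), function(i) {
    idx <- match(docs$tokens[[i]], vocab)
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0L) return(tibble(i = integer(), j = integer(), x = integer()))
    tab <- table(idx)
    tibble(i = i, j = as.integer(names(tab)), x = as.integer(tab))
  })
  Matrix::sparseMatrix(
    i = triplets$i, j = triplets$j, x = triplets$x,
    dims = c(n, length(vocab)),
    dimnames = list(docs$doc_id, vocab)
  )
}
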
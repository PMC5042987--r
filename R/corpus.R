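#' Read a timestamped document corpus
#'
#' Reads a longitudinal corpus with one record per document. Each record
#' must carry a unique `id`, an ISO-8601 `date` and a free-text `text`
#' field. JSONL input has one JSON object per line; CSV input has the same
#' three named columns.
#'
#' @param path Path to the corpus file.
#' @param format `"jsonl"` or `"csv"`; default guessed from the file
#'   extension.
#' @return A tibble with columns `doc_id` (character), `date` (`Date`) and
#'   `text` (character), one row per document.
#' @details Malformed records are hard errors naming the offending line:
#'   a corpus with silently dropped documents would bias every epoch's
#'   topic weights downstream. An empty file yields an empty tibble with a
#'   warning.
#' @export
read_corpus <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("Corpus file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  docs <- if (format == "jsonl") read_corpus_jsonl(path) else read_corpus_csv(path)
  if (nrow(docs) == 0L) {
    warn(sprintf("Corpus file %s contains no documents.", path))
    return(docs)
  }
  dup <- docs$doc_id[duplicated(docs$doc_id)]
  if (length(dup) > 0L) {
    abort(sprintf("Duplicate document id(s): %s", paste(unique(dup), collapse = ", ")))
  }
  docs
}

read_corpus_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines_keep <- which(nzchar(trimws(lines)))
  recs <- purrr::map(lines_keep, function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) abort(sprintf("Line %d: invalid JSON (%s)", i, conditionMessage(e))))
    for (f in c("id", "date", "text")) {
      if (is.null(rec[[f]])) abort(sprintf("Line %d: missing field '%s'", i, f))
    }
    d <- parse_corpus_date(rec$date)
    if (is.na(d)) abort(sprintf("Line %d: unparseable date '%s'", i, rec$date))
    tibble(doc_id = as.character(rec$id), date = d, text = as.character(rec$text))
  })
  if (length(recs) == 0L) {
    return(tibble(doc_id = character(), date = as.Date(character()), text = character()))
  }
  dplyr::bind_rows(recs)
}

read_corpus_csv <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  for (f in c("id", "date", "text")) {
    if (!f %in% names(raw)) abort(sprintf("CSV corpus must have column '%s'", f))
  }
  if (nrow(raw) == 0L) {
    return(tibble(doc_id = character(), date = as.Date(character()), text = character()))
  }
  d <- parse_corpus_date(raw$date)
  if (anyNA(d)) {
    # +1 for the header line so the number matches the file
    abort(sprintf("Unparseable date on line(s): %s",
                  paste(which(is.na(d)) + 1L, collapse = ", ")))
  }
  tibble(doc_id = raw$id, date = d, text = raw$text)
}

parse_corpus_date <- function(x) {
  suppressWarnings(as.Date(as.character(x), format = "%Y-%m-%d"))
}

#' Write a corpus to JSONL
#'
#' @param docs Tibble with `doc_id`, `date`, `text` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(docs, path) {
  lines <- purrr::pmap_chr(docs[c("doc_id", "date", "text")], function(doc_id, date, text) {
    jsonlite::toJSON(list(id = doc_id, date = format(date, "%Y-%m-%d"), text = text),
                     auto_unbox = TRUE)
  })
  writeLines(lines, path)
  invisible(path)
}

#' Partition a corpus into contiguous, optionally overlapping epochs
#'
#' Discretizes the corpus time line into epochs of fixed length. Epoch
#' `t + 1` starts `epoch_length - overlap` days after epoch `t`, so with
#' `overlap = 0` the epochs tile the corpus span and each document belongs
#' to exactly one epoch; with positive overlap a document can fall into
#' several. Boundaries are half-open `[start, end)` on dates, so a
#' timestamp sitting exactly on a boundary belongs to the later epoch only.
#'
#' There is no principled way to choose `epoch_length` and `overlap`: they
#' depend on the dynamics of the corpus (contrast social-media streams with
#' the medical literature), so both are explicit arguments with no default.
#'
#' @param docs Corpus tibble from [read_corpus()] (needs `doc_id`, `date`).
#' @param epoch_length Epoch duration in days.
#' @param overlap Overlap between consecutive epochs in days,
#'   `0 <= overlap < epoch_length`.
#' @param start,end Optional global date range (`[start, end)`); defaults
#'   to the corpus span. Documents outside the range are skipped with a
#'   warning.
#' @return An object of class `tf_epochs`: a list with `epochs` (tibble
#'   `epoch`, `start`, `end`, `n_docs`) and `assignment` (tibble `doc_id`,
#'   `epoch`).
#' @export
partition_epochs <- function(docs, epoch_length, overlap = 0, start = NULL, end = NULL) {
  if (nrow(docs) == 0L) abort("Cannot partition an empty corpus.")
  epoch_length <- as.numeric(epoch_length)
  overlap <- as.numeric(overlap)
  if (!isTRUE(epoch_length > 0)) abort("`epoch_length` must be positive.")
  if (overlap < 0 || overlap >= epoch_length) {
    abort("`overlap` must satisfy 0 <= overlap < epoch_length.")
  }
  dates <- as.Date(docs$date)
  start <- as.Date(start %||% min(dates))
  end <- as.Date(end %||% (max(dates) + 1L))
  inside <- dates >= start & dates < end
  if (any(!inside)) {
    warn(sprintf("%d document(s) outside [%s, %s) skipped.",
                 sum(!inside), format(start), format(end)))
  }
  docs <- docs[inside, , drop = FALSE]
  dates <- dates[inside]
  if (nrow(docs) == 0L) abort("No documents fall inside the configured date range.")

  stride <- epoch_length - overlap
  starts <- start
  # grow until one epoch's end covers the global end
  while (tail(starts, 1L) + epoch_length < end) {
    starts <- c(starts, tail(starts, 1L) + stride)
  }
  epochs <- tibble(
    epoch = seq_along(starts),
    start = starts,
    end = starts + epoch_length
  )
  assignment <- tidyr::crossing(epoch = epochs$epoch, doc_row = seq_len(nrow(docs))) |>
    dplyr::left_join(epochs, by = "epoch") |>
    dplyr::filter(dates[.data$doc_row] >= .data$start, dates[.data$doc_row] < .data$end) |>
    dplyr::transmute(doc_id = docs$doc_id[.data$doc_row], epoch = .data$epoch)

  # drop empty trailing epochs
  occupied <- sort(unique(assignment$epoch))
  last_occupied <- max(occupied)
  epochs <- dplyr::filter(epochs, .data$epoch <= last_occupied)
  epochs$n_docs <- vapply(epochs$epoch, function(t) sum(assignment$epoch == t), integer(1))

  structure(list(epochs = epochs, assignment = assignment), class = "tf_epochs")
}

#' @export
print.tf_epochs <- function(x, ...) {
  cat(sprintf("<tf_epochs> %d epochs, %d document assignments\n",
              nrow(x$epochs), nrow(x$assignment)))
  print(x$epochs)
  invisible(x)
}

#' Write the epoch assignment table as CSV
#'
#' @param epochs A `tf_epochs` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_epoch_assignment <- function(epochs, path) {
  stopifnot(inherits(epochs, "tf_epochs"))
  readr::write_csv(epochs$assignment, path)
  invisible(path)
}
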
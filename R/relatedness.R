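#' Bhattacharyya distance between two discrete distributions
#'
#' The Bhattacharyya distance (BHD) between probability vectors `p` and `q`
#' over the same outcome space is \eqn{-\ln \sum_i \sqrt{p_i q_i}}. It is
#' symmetric, zero iff `p == q`, and `+Inf` iff the supports are disjoint.
#' It is the symmetric relatedness measure used on the temporal topic graph:
#' small values mean strongly overlapping topics.
#'
#' @param p,q Numeric probability vectors of equal length (non-negative,
#'   summing to 1 within `1e-6`).
#' @param validate Check the simplex invariants (default `TRUE`). Turn off
#'   only in tight loops over vectors already known to be valid.
#' @return A non-negative scalar, possibly `Inf`. Distances are measured in
#'   nats (natural logarithm).
#' @seealso [kld()] for the asymmetric companion measure, and
#'   [pairwise_weights()] for whole topic sets.
#' @examples
#' bhattacharyya(c(.5, .5), c(.9, .1))
#' bhattacharyya(c(1, 0), c(0, 1))  # disjoint supports -> Inf
#' @export
bhattacharyya <- function(p, q, validate = TRUE) {
  if (validate) {
    check_distribution(p, "p")
    check_distribution(q, "q")
  }
  if (length(p) != length(q)) {
    abort("`p` and `q` must be distributions over the same vocabulary (equal length).")
  }
  bc <- sum(sqrt(p * q))
  if (bc <= 0) return(Inf)
  max(-log(bc), 0)
}

#' Kullback-Leibler divergence between two discrete distributions
#'
#' \eqn{\mathrm{KLD}(p \| q) = \sum_i p_i \ln(p_i / q_i)}, with the
#' convention \eqn{0 \ln(0/q) = 0}. Asymmetric: a high penalty is incurred
#' where `p` carries mass and `q` does not, and the divergence is `+Inf`
#' whenever some outcome has `p > 0` but `q = 0`. This directionality is
#' what lets the temporal graph expose abrupt topic splitting and merging,
#' which are invisible to a symmetric overlap measure: a child topic whose
#' support sits inside its parent's has a small `kld(child, parent)` even
#' though `kld(parent, child)` is large.
#'
#' @inheritParams bhattacharyya
#' @return A non-negative scalar in nats, possibly `Inf`.
#' @examples
#' kld(c(.5, .5), c(.25, .75))
#' kld(c(.5, .5), c(1, 0))  # q lacks support where p has mass -> Inf
#' @export
kld <- function(p, q, validate = TRUE) {
  if (validate) {
    check_distribution(p, "p")
    check_distribution(q, "q")
  }
  if (length(p) != length(q)) {
    abort("`p` and `q` must be distributions over the same vocabulary (equal length).")
  }
  s <- p > 0
  if (any(q[s] == 0)) return(Inf)
  max(sum(p[s] * (log(p[s]) - log(q[s]))), 0)
}

check_distribution <- function(x, name) {
  if (!is.numeric(x) || length(x) < 1L) {
    abort(sprintf("`%s` must be a non-empty numeric vector.", name))
  }
  if (anyNA(x) || any(x < 0)) {
    abort(sprintf("`%s` must be non-negative with no missing values.", name))
  }
  if (abs(sum(x) - 1) > 1e-6) {
    abort(sprintf("`%s` must sum to 1 (observed %.8f).", name, sum(x)))
  }
  invisible(x)
}

#' Construct a per-epoch topic set
#'
#' Bundles an epoch's topic-term distributions with their popularity
#' weights. Rows of `phi` are topics over a shared vocabulary; `weights`
#' is the fraction of the epoch's tokens each topic accounts for.
#'
#' @param phi Numeric matrix, one row per topic, columns indexed by the
#'   vocabulary; each row must sum to 1.
#' @param weights Popularity weights, one per topic, summing to 1.
#' @param epoch Integer epoch index (1-based).
#' @param vocab Optional character vector of terms (column names).
#' @param topic_ids Optional topic identifiers; default `"e<epoch>.k<row>"`.
#' @return An object of class `tf_topics`.
#' @export
topic_set <- function(phi, weights = NULL, epoch = 1L, vocab = NULL,
                      topic_ids = NULL) {
  phi <- as.matrix(phi)
  if (nrow(phi) < 1L) abort("A topic set needs at least one topic.")
  rs <- rowSums(phi)
  if (any(phi < 0) || any(abs(rs - 1) > 1e-6)) {
    abort("Every row of `phi` must be a probability distribution summing to 1.")
  }
  if (is.null(weights)) weights <- rep(1 / nrow(phi), nrow(phi))
  if (length(weights) != nrow(phi) || abs(sum(weights) - 1) > 1e-6) {
    abort("`weights` must have one entry per topic and sum to 1.")
  }
  if (!is.null(vocab)) {
    if (length(vocab) != ncol(phi)) abort("`vocab` length must match ncol(phi).")
    colnames(phi) <- vocab
  }
  if (is.null(topic_ids)) {
    topic_ids <- sprintf("e%d.k%d", epoch, seq_len(nrow(phi)))
  }
  rownames(phi) <- topic_ids
  structure(
    list(phi = phi, weights = setNames(as.numeric(weights), topic_ids),
         epoch = as.integer(epoch), vocab = colnames(phi)),
    class = "tf_topics"
  )
}

#' @export
print.tf_topics <- function(x, ...) {
  cat(sprintf("<tf_topics> epoch %d: %d topics over %d terms\n",
              x$epoch, nrow(x$phi), ncol(x$phi)))
  invisible(x)
}

#' @export
tidy.tf_topics <- function(x, n_terms = 8L, ...) {
  purrr::map_dfr(seq_len(nrow(x$phi)), function(k) {
    ord <- order(x$phi[k, ], decreasing = TRUE)[seq_len(min(n_terms, ncol(x$phi)))]
    tibble(
      epoch = x$epoch,
      topic = rownames(x$phi)[k],
      popularity = unname(x$weights[k]),
      term = colnames(x$phi)[ord] %||% as.character(ord),
      prob = unname(x$phi[k, ord]),
      rank = seq_along(ord)
    )
  })
}

#' Pairwise relatedness weights between two adjacent-epoch topic sets
#'
#' Computes the full weight matrix linking every topic of epoch `t` (rows)
#' to every topic of epoch `t + 1` (columns) under one of three metrics:
#'
#' * `"bhd"` — Bhattacharyya distance `bhd(phi_j, phi_k)` (symmetric);
#' * `"kld_forward"` — `kld(phi_k[t+1], phi_j[t])`: information lost when
#'   the later topic is approximated by the earlier one, so a child whose
#'   support is contained in its parent's gets a small weight (the
#'   splitting signature);
#' * `"kld_backward"` — `kld(phi_j[t], phi_k[t+1])`: the mirror image,
#'   small when an earlier topic's support sits inside a later topic's
#'   (the merging signature).
#'
#' @param A,B `tf_topics` for epochs `t` and `t + 1`, over the same
#'   vocabulary.
#' @param metric One of `"bhd"`, `"kld_forward"`, `"kld_backward"`.
#' @return A `nrow(A$phi) x nrow(B$phi)` matrix with topic-id dimnames.
#'   Entries may be `Inf` for distributions with mismatched support (never
#'   the case for smoothed posterior topic estimates).
#' @export
pairwise_weights <- function(A, B, metric = c("bhd", "kld_forward", "kld_backward")) {
  metric <- match.arg(metric)
  stopifnot(inherits(A, "tf_topics"), inherits(B, "tf_topics"))
  if (ncol(A$phi) != ncol(B$phi) ||
      (!is.null(A$vocab) && !is.null(B$vocab) && !identical(A$vocab, B$vocab))) {
    abort("Topic sets must share the same vocabulary.")
  }
  w <- switch(metric,
    bhd          = bhd_matrix(A$phi, B$phi),
    kld_forward  = t(kld_matrix(B$phi, A$phi)),
    kld_backward = kld_matrix(A$phi, B$phi)
  )
  dimnames(w) <- list(rownames(A$phi), rownames(B$phi))
  w
}

# -ln( sqrt(P) %*% t(sqrt(Q)) ), elementwise over topic rows
bhd_matrix <- function(P, Q) {
  bc <- sqrt(P) %*% t(sqrt(Q))
  w <- -log(bc)              # bc = 0 -> Inf, as required for disjoint supports
  w[w < 0] <- 0              # guard float round-off for identical rows
  w
}

# out[a, b] = kld(P[a, ], Q[b, ]); exact +Inf where P has mass off Q's support
kld_matrix <- function(P, Q) {
  ent <- rowSums(ifelse(P > 0, P * log(P), 0))    # sum p log p per row of P
  logQ <- t(ifelse(Q > 0, log(Q), 0))
  cross <- P %*% logQ
  w <- ent - cross
  bad <- (P > 0) %*% t(Q == 0)                    # support violations -> Inf
  w[bad > 0] <- Inf
  w[w < 0] <- 0
  w
}
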
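#' Specify a planted-dynamics synthetic corpus
#'
#' Defines a longitudinal corpus generated from per-epoch planted topics
#' whose lineages exhibit scripted evolution phenomena: stable
#' persistence, gradual drift, emergence, disappearance, abrupt splitting
#' (support partition), abrupt merging (support union), gradual speciation
#' (two descendants of one parent drifting apart) and gradual convergence
#' (two topics approaching, then fusing). Every pipeline stage can be
#' validated against the resulting ground truth without any external data.
#'
#' Each root lineage owns a disjoint block of `block_size` vocabulary
#' terms and starts uniform on its block; the vocabulary size is the sum
#' of all block sizes. Event children derive their support from their
#' parents (split children partition it, merge/convergence children
#' combine it, speciation children inherit it), so they own no block.
#'
#' @param lineages Tibble with columns `name`, `block_size`, `behaviour`
#'   (`"stable"` or `"drift"`), `from`, `to` (first/last epoch present;
#'   `from > 1` plants an emergence, `to < n_epochs` a disappearance).
#' @param events Tibble with columns `kind` (`"split"`, `"merge"`,
#'   `"speciate"`, `"converge"`), `epoch` (the transition: parents present
#'   through `epoch`, children from `epoch + 1`), `parents`, `children`
#'   (list-columns of lineage names).
#' @param n_epochs Number of epochs.
#' @param docs_per_epoch,doc_length Documents per epoch and tokens per
#'   document.
#' @param doc_concentration Symmetric Dirichlet concentration of the
#'   per-document topic mixture (default 0.3: documents concentrate on
#'   one or two topics, as abstracts do).
#' @param drift_weight Default per-epoch mixing weight of a drifting topic
#'   toward a fresh Dirichlet draw (0.1; lineages can override via a
#'   `drift` column). Small weights keep consecutive-epoch distance well
#'   below cross-topic distance; large weights (~0.3) model fast-moving
#'   topics whose novelty is visible to the directed divergence but barely
#'   dents symmetric overlap.
#' @param drift_conc Default concentration of the fresh Dirichlet draw
#'   used for drift (1 = diffuse novelty; lineages can override via a
#'   `drift_conc` column, e.g. 0.05 for novelty concentrated on a couple
#'   of terms).
#' @param speciate_start Fraction of the way a speciation child starts
#'   toward its own sub-support at birth (default 0.7), making the
#'   children immediately distinguishable yet both clearly similar to
#'   their parent.
#' @param speciate_weight Per-epoch weight with which speciation children
#'   continue toward their sub-supports (default 0.35).
#' @param approach_weight Per-epoch weight with which converging parents
#'   move toward their common target (default 0.35).
#' @param umbrella_core Mass an umbrella lineage places on its own core
#'   block (default 0.4), the rest spread uniformly over the blocks it
#'   spans. A strictly positive core keeps a broad topic statistically
#'   identifiable: with no core, its documents are exactly reproduced by
#'   a mixture of the spanned topics and the model rightly never
#'   instantiates it.
#' @param epoch_length_days,start_date Calendar geometry used to place
#'   document timestamps.
#' @param seed Base seed; generation is fully reproducible given the spec.
#' @return A list of class `tf_dynamics_spec`.
#' @seealso [demo_dynamics_spec()], [basic_dynamics_spec()],
#'   [make_planted_topics()], [sample_documents()].
#' @export
planted_dynamics_spec <- function(lineages, events = NULL, n_epochs,
                                  docs_per_epoch = 200L, doc_length = 50L,
                                  doc_concentration = 0.3,
                                  drift_weight = 0.1, drift_conc = 1,
                                  speciate_start = 0.7, speciate_weight = 0.35,
                                  approach_weight = 0.35, umbrella_core = 0.4,
                                  epoch_length_days = 100L,
                                  start_date = as.Date("2000-01-01"),
                                  seed = 42L) {
  lineages <- as_tibble(lineages)
  need <- c("name", "block_size", "behaviour", "from", "to")
  if (!all(need %in% names(lineages))) {
    abort(sprintf("`lineages` needs columns %s.", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(lineages$name)) abort("Lineage names must be unique.")
  if (!"drift" %in% names(lineages)) lineages$drift <- NA_real_
  if (!"drift_conc" %in% names(lineages)) lineages$drift_conc <- NA_real_
  if (!"span" %in% names(lineages)) lineages$span <- rep(list(NULL), nrow(lineages))
  lineages$span <- purrr::map(lineages$span, identity)
  lineages$drift <- dplyr::coalesce(lineages$drift, drift_weight)
  lineages$drift_conc <- dplyr::coalesce(lineages$drift_conc, drift_conc)
  if (is.null(events)) {
    events <- tibble(kind = character(), epoch = integer(),
                     parents = list(), children = list())
  }
  spec <- structure(
    list(lineages = lineages, events = as_tibble(events),
         n_epochs = as.integer(n_epochs),
         docs_per_epoch = as.integer(docs_per_epoch),
         doc_length = as.integer(doc_length),
         doc_concentration = doc_concentration,
         drift_weight = drift_weight, drift_conc = drift_conc,
         speciate_start = speciate_start, speciate_weight = speciate_weight,
         approach_weight = approach_weight, umbrella_core = umbrella_core,
         epoch_length_days = as.integer(epoch_length_days),
         start_date = as.Date(start_date), seed = as.integer(seed),
         V = sum(lineages$block_size)),
    class = "tf_dynamics_spec"
  )
  validate_dynamics_spec(spec)
  spec
}

validate_dynamics_spec <- function(spec) {
  ln <- spec$lineages
  if (any(ln$from < 1L | ln$to > spec$n_epochs | ln$from > ln$to)) {
    abort("Lineage lifetimes must satisfy 1 <= from <= to <= n_epochs.")
  }
  if (!all(ln$behaviour %in% c("stable", "drift"))) {
    abort("Lineage behaviour must be 'stable' or 'drift'.")
  }
  for (i in seq_len(nrow(ln))) {
    sp <- ln$span[[i]]
    if (is.null(sp)) {
      if (ln$block_size[i] < 1L) abort(sprintf("Lineage '%s' needs a positive block_size.", ln$name[i]))
    } else {
      missing <- setdiff(sp, ln$name)
      if (length(missing)) {
        abort(sprintf("Umbrella lineage '%s' spans unknown lineage '%s'.", ln$name[i], missing[1]))
      }
      if (any(vapply(ln$span[match(sp, ln$name)], Negate(is.null), logical(1)))) {
        abort(sprintf("Umbrella lineage '%s' may only span block lineages.", ln$name[i]))
      }
    }
  }
  ev <- spec$events
  if (nrow(ev) == 0L) return(invisible(spec))
  if (!all(ev$kind %in% c("split", "merge", "speciate", "converge"))) {
    abort(sprintf("Unknown event kind '%s'.",
                  setdiff(ev$kind, c("split", "merge", "speciate", "converge"))[1]))
  }
  all_children <- unlist(ev$children)
  if (anyDuplicated(all_children)) {
    abort(sprintf("Event child '%s' defined more than once.",
                  all_children[duplicated(all_children)][1]))
  }
  clash <- intersect(all_children, ln$name)
  if (length(clash)) abort(sprintf("Event child '%s' collides with a lineage name.", clash[1]))
  for (i in seq_len(nrow(ev))) {
    k <- ev$kind[i]; t <- ev$epoch[i]
    np <- length(ev$parents[[i]]); nc <- length(ev$children[[i]])
    if (t < 1L || t >= spec$n_epochs) {
      abort(sprintf("Event %d (%s): transition epoch %d outside 1..%d.",
                    i, k, t, spec$n_epochs - 1L))
    }
    ok <- switch(k,
                 split = np == 1L && nc >= 2L,
                 speciate = np == 1L && nc >= 2L,
                 merge = np >= 2L && nc == 1L,
                 converge = np >= 2L && nc == 1L)
    if (!ok) abort(sprintf("Event %d (%s): wrong participant arity.", i, k))
    for (p in ev$parents[[i]]) {
      row <- ln[ln$name == p, ]
      if (nrow(row) == 0L) {
        abort(sprintf("Event %d (%s): parent '%s' is not a root lineage (chained events are not supported).",
                      i, k, p))
      }
      if (row$from > t || row$to != t) {
        abort(sprintf(
          "Event %d (%s): parent '%s' must be present through transition epoch %d (set its `to` to %d).",
          i, k, p, t, t))
      }
    }
  }
  invisible(spec)
}

#' @export
print.tf_dynamics_spec <- function(x, ...) {
  cat(sprintf("<tf_dynamics_spec> V = %d, %d epochs, %d root lineages, %d scripted events, %d docs/epoch x %d tokens\n",
              x$V, x$n_epochs, nrow(x$lineages), nrow(x$events),
              x$docs_per_epoch, x$doc_length))
  invisible(x)
}

rdirichlet1 <- function(n, alpha) {
  g <- rgamma(n, shape = alpha, rate = 1)
  if (sum(g) <= 0) g[sample.int(n, 1L)] <- 1
  g / sum(g)
}

synthetic_vocab <- function(V) {
  # letter-only terms so they survive text tokenization, prefixed to avoid
  # colliding with the default stop-word list
  stopifnot(V <= 26L * 26L)
  grid <- expand.grid(a = letters, b = letters, stringsAsFactors = FALSE)
  paste0("zz", grid$b, grid$a)[seq_len(V)]
}

#' Realize the planted topics and ground-truth event log of a spec
#'
#' Walks the scripted timeline epoch by epoch: root lineages appear
#' uniform on their support blocks (umbrella lineages uniform over the
#' union of the blocks they span) and then persist (stable) or drift (mix
#' with a fresh Dirichlet draw at their per-lineage weight and
#' concentration); split parents are partitioned into disjoint
#' renormalized children (terms allocated to children round-robin by
#' descending parent mass, so child masses are balanced); merge children
#' are equal-weight mixtures of their parents; speciation children start
#' `speciate_start` of the way toward complementary sub-supports of their
#' parent and keep moving toward them (gradual differentiation, the
#' counterpart of the abrupt split); convergence parents move toward
#' their common midpoint until they fuse into one child. Event children
#' inherit the drift parameters of their (first) parent.
#'
#' @param spec A [planted_dynamics_spec()].
#' @param seed Seed for the drift/direction draws; defaults to the spec's.
#' @return An object of class `tf_ground_truth`: `topics` (list of
#'   `tf_topics` per epoch, ids `"e<t>.<lineage>"`), `lineages` (tibble
#'   `epoch`, `topic_id`, `lineage`), `events` (ground-truth event log in
#'   the conventions of [classify_events()], including the `evolved`
#'   events implied by 1-to-1 lineage continuation), `split_detail`
#'   (per-child retained parent mass, for analytic checks), `vocab`, and
#'   the `spec`.
#' @export
make_planted_topics <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "tf_dynamics_spec"))
  set.seed(as.integer(seed))
  V <- spec$V
  vocab <- synthetic_vocab(V)
  ln <- spec$lineages

  # disjoint support blocks, allocated in lineage order
  offsets <- cumsum(c(0L, ln$block_size))
  blocks <- purrr::map(seq_len(nrow(ln)), function(i) (offsets[i] + 1L):offsets[i + 1L])
  names(blocks) <- ln$name

  uniform_on <- function(idx) {
    p <- numeric(V); p[idx] <- 1 / length(idx); p
  }

  # convergence targets are midpoints of the parents' initial distributions
  conv_target <- list()
  ev <- spec$events
  init_p <- function(i) {
    sp <- ln$span[[i]]
    if (is.null(sp)) return(uniform_on(blocks[[ln$name[i]]]))
    wide <- uniform_on(sort(unlist(blocks[sp])))
    if (ln$block_size[i] == 0L) return(wide)
    core <- uniform_on(blocks[[ln$name[i]]])
    spec$umbrella_core * core + (1 - spec$umbrella_core) * wide
  }
  for (i in seq_len(nrow(ev))) {
    if (ev$kind[i] == "converge") {
      ps <- ev$parents[[i]]
      m <- Reduce(`+`, purrr::map(match(ps, ln$name), init_p)) / length(ps)
      for (p in ps) conv_target[[p]] <- m
    }
  }

  # name -> list(p, update = "stable"|"drift"|"approach", w, conc, target)
  active <- list()
  topics <- vector("list", spec$n_epochs)
  lineage_rows <- list()
  truth_events <- list()
  split_detail <- list()

  evolve_one <- function(tp) {
    p <- switch(tp$update,
      stable = tp$p,
      drift = (1 - tp$w) * tp$p + tp$w * rdirichlet1(V, tp$conc),
      approach = (1 - tp$w) * tp$p + tp$w * tp$target
    )
    tp$p <- p / sum(p)
    tp
  }

  # partition a distribution's support into n renormalized sub-distributions,
  # terms dealt round-robin by descending mass so the pieces are balanced
  partition_support <- function(p, n) {
    supp <- which(p > 0)
    supp <- supp[order(-p[supp])]
    purrr::map(seq_len(n), function(j) {
      idx <- supp[seq(j, length(supp), by = n)]
      mass <- sum(p[idx])
      q <- numeric(V)
      q[idx] <- p[idx] / mass
      list(q = q, mass = mass)
    })
  }

  for (t in seq_len(spec$n_epochs)) {
    # births of root lineages
    for (i in which(ln$from == t)) {
      nm <- ln$name[i]
      if (!is.null(conv_target[[nm]])) {
        st <- list(p = init_p(i), update = "approach", w = spec$approach_weight,
                   conc = ln$drift_conc[i], target = conv_target[[nm]])
      } else {
        st <- list(p = init_p(i), update = ln$behaviour[i], w = ln$drift[i],
                   conc = ln$drift_conc[i], target = NULL)
      }
      active[[nm]] <- st
      if (t > 1L) {
        truth_events[[length(truth_events) + 1L]] <-
          tibble(kind = "emerged", epoch = t, parents = list(character(0)),
                 children = list(nm))
      }
    }

    # record epoch t
    nm <- names(active)
    phi <- do.call(rbind, purrr::map(active, "p"))
    topics[[t]] <- topic_set(phi, epoch = t, vocab = vocab,
                             topic_ids = sprintf("e%d.%s", t, nm))
    lineage_rows[[t]] <- tibble(epoch = t, topic_id = sprintf("e%d.%s", t, nm),
                                lineage = nm)
    if (t == spec$n_epochs) break

    # transition t -> t + 1
    consumed <- character(0)
    for (i in seq_len(nrow(ev))) {
      if (ev$epoch[i] != t) next
      kind <- ev$kind[i]; ps <- ev$parents[[i]]; cs <- ev$children[[i]]
      consumed <- c(consumed, ps)
      inherit <- active[[ps[1]]]
      if (kind == "split") {
        pieces <- partition_support(active[[ps]]$p, length(cs))
        for (j in seq_along(cs)) {
          active[[cs[j]]] <- list(p = pieces[[j]]$q, update = inherit$update,
                                  w = inherit$w, conc = inherit$conc, target = NULL)
          split_detail[[length(split_detail) + 1L]] <-
            tibble(parent = ps, child = cs[j], epoch = t,
                   retained_mass = pieces[[j]]$mass)
        }
        truth_events[[length(truth_events) + 1L]] <-
          tibble(kind = "split", epoch = t, parents = list(ps), children = list(sort(cs)))
      } else if (kind == "speciate") {
        parent <- active[[ps]]$p
        pieces <- partition_support(parent, length(cs))
        s0 <- spec$speciate_start
        for (j in seq_along(cs)) {
          p0 <- (1 - s0) * parent + s0 * pieces[[j]]$q
          active[[cs[j]]] <- list(p = p0 / sum(p0), update = "approach",
                                  w = spec$speciate_weight, conc = inherit$conc,
                                  target = pieces[[j]]$q)
        }
        truth_events[[length(truth_events) + 1L]] <-
          tibble(kind = "speciated", epoch = t, parents = list(ps), children = list(sort(cs)))
      } else if (kind == "merge" || kind == "converge") {
        child <- Reduce(`+`, purrr::map(ps, function(p) active[[p]]$p)) / length(ps)
        active[[cs]] <- list(p = child / sum(child), update = inherit$update,
                             w = inherit$w, conc = inherit$conc, target = NULL)
        truth_events[[length(truth_events) + 1L]] <-
          tibble(kind = if (kind == "merge") "merged" else "converged",
                 epoch = t + 1L, parents = list(sort(ps)), children = list(cs))
      }
    }
    # disappearances (lineages whose lifetime ends at t, not consumed by an event)
    dying <- setdiff(ln$name[ln$to == t], consumed)
    for (nm2 in dying) {
      truth_events[[length(truth_events) + 1L]] <-
        tibble(kind = "vanished", epoch = t, parents = list(nm2),
               children = list(character(0)))
    }
    # survivors continue 1-to-1: the implied gradual-evolution events
    new_children <- unlist(ev$children[ev$epoch == t]) %||% character(0)
    survivors <- setdiff(names(active), c(consumed, dying, new_children))
    for (nm2 in survivors) {
      truth_events[[length(truth_events) + 1L]] <-
        tibble(kind = "evolved", epoch = t, parents = list(nm2), children = list(nm2))
    }
    active <- active[setdiff(names(active), c(consumed, dying))]
    # children created at this transition enter epoch t + 1 exactly as
    # constructed (their closed-form signatures must survive intact);
    # everyone else takes its per-epoch update step
    for (nm2 in setdiff(names(active), new_children)) {
      active[[nm2]] <- evolve_one(active[[nm2]])
    }
  }

  structure(
    list(spec = spec, vocab = vocab,
         topics = topics,
         lineages = dplyr::bind_rows(lineage_rows),
         events = dplyr::bind_rows(truth_events),
         split_detail = if (length(split_detail)) dplyr::bind_rows(split_detail)
                        else tibble(parent = character(), child = character(),
                                    epoch = integer(), retained_mass = numeric())),
    class = "tf_ground_truth"
  )
}

#' @export
print.tf_ground_truth <- function(x, ...) {
  cat(sprintf("<tf_ground_truth> V = %d, %d epochs; topics per epoch: %s; %d truth events\n",
              x$spec$V, length(x$topics),
              paste(vapply(x$topics, function(s) nrow(s$phi), integer(1)), collapse = ", "),
              nrow(x$events)))
  invisible(x)
}

#' Sample a timestamped document corpus from planted topics
#'
#' Generates `docs_per_epoch` documents per epoch under the mixture model:
#' each document draws a topic mixture from a symmetric Dirichlet over the
#' epoch's planted topics, then each token draws its topic and its term.
#' Timestamps are placed deterministically inside the epoch's calendar
#' interval. Fully reproducible from the seed.
#'
#' @param truth A `tf_ground_truth` from [make_planted_topics()].
#' @param seed Seed for document sampling; defaults to the spec's seed
#'   plus 1 (so topics and documents use distinct streams).
#' @return A tibble (`doc_id`, `date`, `epoch`, `text`, `tokens`), tokens
#'   as a list-column; the true document-topic mixtures are attached as
#'   attribute `"theta"` (one matrix per epoch).
#' @export
sample_documents <- function(truth, seed = truth$spec$seed + 1L) {
  stopifnot(inherits(truth, "tf_ground_truth"))
  spec <- truth$spec
  set.seed(as.integer(seed))
  out <- vector("list", spec$n_epochs)
  thetas <- vector("list", spec$n_epochs)
  for (t in seq_len(spec$n_epochs)) {
    ts <- truth$topics[[t]]
    K <- nrow(ts$phi)
    n <- spec$docs_per_epoch
    L <- spec$doc_length
    theta <- t(replicate(n, rdirichlet1(K, spec$doc_concentration)))
    if (K == 1L) theta <- matrix(1, n, 1L)
    tokens <- vector("list", n)
    for (d in seq_len(n)) {
      z <- sample.int(K, L, replace = TRUE, prob = theta[d, ])
      w <- integer(L)
      for (k in unique(z)) {
        sel <- z == k
        w[sel] <- sample.int(spec$V, sum(sel), replace = TRUE, prob = ts$phi[k, ])
      }
      tokens[[d]] <- truth$vocab[w]
    }
    day0 <- spec$start_date + (t - 1L) * spec$epoch_length_days
    dates <- day0 + floor((seq_len(n) - 0.5) / n * spec$epoch_length_days)
    out[[t]] <- tibble(
      doc_id = sprintf("e%d_d%04d", t, seq_len(n)),
      date = dates, epoch = t,
      text = vapply(tokens, paste, "", collapse = " "),
      tokens = tokens
    )
    rownames(theta) <- out[[t]]$doc_id
    thetas[[t]] <- theta
  }
  docs <- dplyr::bind_rows(out)
  attr(docs, "theta") <- thetas
  docs
}

#' Generate a complete synthetic corpus with ground truth
#'
#' Convenience wrapper: [make_planted_topics()] then [sample_documents()].
#'
#' @param spec A [planted_dynamics_spec()].
#' @param seed Overrides the spec seed for both stages when given.
#' @return A list with `docs` (corpus tibble) and `truth`
#'   (`tf_ground_truth`).
#' @export
synth_corpus <- function(spec, seed = spec$seed) {
  truth <- make_planted_topics(spec, seed = seed)
  docs <- sample_documents(truth, seed = seed + 1L)
  list(docs = docs, truth = truth)
}

#' Canonical multi-phenomenon demonstration script
#'
#' A 5-epoch script planting every evolution phenomenon at once over a
#' 61-term vocabulary with 9 to 12 topics per epoch:
#'
#' * `S` — a stable topic that splits abruptly four ways (`Sa`..`Sd`)
#'   after epoch 2: the hard support partition that only the directed
#'   divergence can see;
#' * `P` — a stable topic that speciates after epoch 1 into `Pa`/`Pb`,
#'   which differentiate gradually toward complementary halves of its
#'   support: the branching that similarity (BHD) tracks;
#' * `C1`/`C2` — two topics converging gradually until they fuse into `C`
#'   after epoch 4;
#' * `M1`/`M2` — two fast-moving topics merged abruptly into `M12` after
#'   epoch 3;
#' * `Vn` (vanishes after epoch 2), `Em` (emerges in epoch 4), `F1` (a
#'   fast "novelty" lineage present throughout);
#' * `U` — a broad umbrella topic with a small core vocabulary of its own
#'   plus the `M1`, `M2` and `Vn` blocks: the survey-like topic that
#'   contains narrower ones.
#'
#' The composition is deliberate. At the usual operating point
#' `zeta = 0.9` the pruned graph keeps a tenth of the candidate edges, so
#' the retained budget (~0.1 K^2 per epoch pair) must comfortably cover
#' the persisting lineages (~K per pair); that fixes roughly ten topics
#' per epoch. Fast-moving lineages and the umbrella create connections on
#' which the two relatedness measures disagree (large divergence despite
#' strong overlap, and strong containment despite weak overlap), giving
#' the BHD and KLD graphs distinct structure at a common operating point.
#' The four-way split places its signature weights (BHD
#' \eqn{\frac{1}{2}\ln 4 \approx 0.69}, forward KLD
#' \eqn{\ln 4 \approx 1.39}) clear of the continuation cluster on the
#' BHD side and clear of the threshold on the KLD side.
#'
#' @inheritParams planted_dynamics_spec
#' @return A `tf_dynamics_spec`.
#' @export
demo_dynamics_spec <- function(docs_per_epoch = 200L, doc_length = 50L, seed = 42L) {
  fast <- 0.25
  fast_conc <- 0.3
  slow <- 0.05
  lineages <- tibble(
    name = c("S", "P", "C1", "C2", "M1", "M2", "Vn", "Em", "F1", "U"),
    block_size = c(12L, 10L, 5L, 5L, 5L, 5L, 5L, 5L, 5L, 4L),
    behaviour = c("stable", "stable", rep("drift", 7L), "drift"),
    from = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 4L, 1L, 1L),
    to = c(2L, 1L, 4L, 4L, 3L, 3L, 2L, 5L, 5L, 5L),
    drift = c(NA, NA, slow, slow, fast, fast, slow, slow, fast, slow),
    drift_conc = c(NA, NA, 1, 1, fast_conc, fast_conc, 1, 1, fast_conc, 1),
    span = c(rep(list(NULL), 9), list(c("M1", "M2", "Vn")))
  )
  events <- tibble(
    kind = c("split", "speciate", "converge", "merge"),
    epoch = c(2L, 1L, 4L, 3L),
    parents = list("S", "P", c("C1", "C2"), c("M1", "M2")),
    children = list(c("Sa", "Sb", "Sc", "Sd"), c("Pa", "Pb"), "C", "M12")
  )
  planted_dynamics_spec(lineages, events, n_epochs = 5L,
                        docs_per_epoch = docs_per_epoch,
                        doc_length = doc_length, seed = seed)
}

#' Minimal single-epoch recovery script
#'
#' Three stable topics with disjoint support over a 50-term vocabulary in
#' one epoch — the basic parameter-recovery setting for the HDP sampler
#' (200 documents of 50 tokens by default).
#'
#' @param n_topics Number of disjoint-support topics (default 3).
#' @param V Vocabulary size (default 50, split as evenly as possible).
#' @inheritParams planted_dynamics_spec
#' @return A `tf_dynamics_spec`.
#' @export
basic_dynamics_spec <- function(n_topics = 3L, V = 50L, docs_per_epoch = 200L,
                                doc_length = 50L, seed = 42L) {
  sizes <- rep(V %/% n_topics, n_topics)
  sizes[seq_len(V %% n_topics)] <- sizes[seq_len(V %% n_topics)] + 1L
  lineages <- tibble(
    name = sprintf("T%d", seq_len(n_topics)),
    block_size = as.integer(sizes),
    behaviour = "stable", from = 1L, to = 1L
  )
  planted_dynamics_spec(lineages, NULL, n_epochs = 1L,
                        docs_per_epoch = docs_per_epoch,
                        doc_length = doc_length, seed = seed)
}

#' Match inferred topics to planted topics by Bhattacharyya distance
#'
#' Greedy one-to-one assignment per epoch: repeatedly match the globally
#' closest (smallest-BHD) planted/inferred pair and remove both, until one
#' side is exhausted.
#'
#' @param truth A `tf_ground_truth`.
#' @param inferred A `tf_topic_sets` list (or list of `tf_topics`) over
#'   the same vocabulary.
#' @param threshold Distance below which a pair counts as matched
#'   (default 0.2).
#' @return A list of class `tf_matching`: `matching` (tibble `epoch`,
#'   `lineage`, `planted_id`, `inferred_id`, `bhd`, `matched`),
#'   `fraction_matched`, `mean_bhd`.
#' @export
evaluate_topic_recovery <- function(truth, inferred, threshold = 0.2) {
  stopifnot(inherits(truth, "tf_ground_truth"))
  rows <- list()
  for (s in inferred) {
    t <- s$epoch
    planted <- truth$topics[[t]]
    if (is.null(planted)) next
    if (ncol(planted$phi) != ncol(s$phi)) abort("Vocabulary mismatch between truth and inferred topics.")
    D <- bhd_matrix(planted$phi, s$phi)
    nm_p <- rownames(planted$phi)
    nm_i <- rownames(s$phi)
    while (nrow(D) > 0L && ncol(D) > 0L && any(is.finite(D))) {
      ij <- arrayInd(which.min(D), dim(D))
      rows[[length(rows) + 1L]] <- tibble(
        epoch = t,
        lineage = truth$lineages$lineage[match(nm_p[ij[1]], truth$lineages$topic_id)],
        planted_id = nm_p[ij[1]], inferred_id = nm_i[ij[2]],
        bhd = D[ij[1], ij[2]]
      )
      D <- D[-ij[1], -ij[2], drop = FALSE]
      nm_p <- nm_p[-ij[1]]
      nm_i <- nm_i[-ij[2]]
    }
    # planted topics left without a partner
    for (nm in nm_p) {
      rows[[length(rows) + 1L]] <- tibble(
        epoch = t,
        lineage = truth$lineages$lineage[match(nm, truth$lineages$topic_id)],
        planted_id = nm, inferred_id = NA_character_, bhd = Inf
      )
    }
  }
  matching <- dplyr::bind_rows(rows) |>
    dplyr::mutate(matched = is.finite(.data$bhd) & .data$bhd < threshold)
  structure(
    list(matching = matching,
         threshold = threshold,
         fraction_matched = mean(matching$matched),
         mean_bhd = mean(matching$bhd[is.finite(matching$bhd)])),
    class = "tf_matching"
  )
}

#' @export
print.tf_matching <- function(x, ...) {
  cat(sprintf("<tf_matching> %d planted topics, %.0f%% matched at BHD < %.3g (mean matched BHD %.4f)\n",
              nrow(x$matching), 100 * x$fraction_matched, x$threshold, x$mean_bhd))
  invisible(x)
}

#' Precision and recall of detected topic events against ground truth
#'
#' Maps each detected event's participant topics to planted lineages via
#' the recovery matching; a detected event is a true positive when its
#' kind, epoch and full mapped participant sets coincide with a planted
#' event. Events with unmatched participants count against precision.
#'
#' @param truth A `tf_ground_truth`.
#' @param events Detected events from [classify_events()].
#' @param matching A `tf_matching` from [evaluate_topic_recovery()].
#' @return A tibble per event kind: `kind`, `n_true`, `n_detected`, `tp`,
#'   `precision`, `recall` (`NA` where undefined).
#' @export
evaluate_event_recovery <- function(truth, events, matching) {
  stopifnot(inherits(truth, "tf_ground_truth"), inherits(matching, "tf_matching"))
  mp <- matching$matching[matching$matching$matched, ]
  id2lineage <- setNames(mp$lineage, mp$inferred_id)
  map_set <- function(ids) {
    mapped <- unname(id2lineage[ids])
    if (anyNA(mapped)) NULL else sort(mapped)
  }
  truth_keys <- purrr::pmap_chr(truth$events, function(kind, epoch, parents, children) {
    paste(kind, epoch, paste(sort(parents), collapse = ","),
          paste(sort(children), collapse = ","), sep = "|")
  })
  detected_keys <- purrr::pmap_chr(events, function(kind, metric, epoch, parents, children) {
    ps <- map_set(parents)
    cs <- map_set(children)
    if ((length(parents) > 0L && is.null(ps)) || (length(children) > 0L && is.null(cs))) {
      return(NA_character_)  # unmatched participant
    }
    paste(kind, epoch, paste(ps, collapse = ","), paste(cs, collapse = ","), sep = "|")
  })
  kinds <- sort(unique(c(truth$events$kind, events$kind)))
  purrr::map_dfr(kinds, function(k) {
    tk <- truth_keys[truth$events$kind == k]
    dk <- detected_keys[events$kind == k]
    tp <- 0L
    pool <- tk
    for (key in dk) {
      if (!is.na(key) && key %in% pool) {
        tp <- tp + 1L
        pool <- pool[-match(key, pool)]
      }
    }
    tibble(kind = k, n_true = length(tk), n_detected = length(dk), tp = tp,
           precision = if (length(dk)) tp / length(dk) else NA_real_,
           recall = if (length(tk)) tp / length(tk) else NA_real_)
  })
}

#' Write a ground-truth bundle to disk
#'
#' Emits the planted topic matrices (one CSV per epoch) and the event log
#' as CSV, alongside the corpus JSONL written by [write_corpus()].
#'
#' @param truth A `tf_ground_truth`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_topic_sets(truth$topics, dir)
  write_events(truth$events |> dplyr::mutate(metric = "planted", .after = "kind"),
               file.path(dir, "true_events.csv"))
  invisible(dir)
}
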
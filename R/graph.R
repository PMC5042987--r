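#' Build the full inter-epoch topic relatedness graph
#'
#' Connects every topic of each epoch to every topic of the following
#' epoch (a complete bipartite edge set per adjacent pair) and weights the
#' edges with one relatedness metric (see [pairwise_weights()]). This full
#' graph is the input to CDF-based pruning; small weights mean strong
#' relatedness for every metric here.
#'
#' @param topic_sets A `tf_topic_sets` list (or plain list of `tf_topics`)
#'   in epoch order with consecutive epoch indices.
#' @param metric `"bhd"`, `"kld_forward"` or `"kld_backward"`.
#' @return An object of class `tf_temporal_graph`: tibbles `nodes`
#'   (`node`, `epoch`, `popularity`) and `edges` (`from`, `to`,
#'   `from_epoch`, `to_epoch`, `weight`), plus `metric`, `pruned`, `zeta`.
#' @export
build_full_graph <- function(topic_sets, metric = c("bhd", "kld_forward", "kld_backward")) {
  metric <- match.arg(metric)
  if (length(topic_sets) < 2L) abort("Need at least two epochs to build a temporal graph.")
  epochs <- vapply(topic_sets, function(s) s$epoch, integer(1))
  if (any(diff(epochs) != 1L)) abort("Topic sets must cover consecutive epochs in order.")

  nodes <- purrr::map_dfr(topic_sets, function(s) {
    tibble(node = rownames(s$phi), epoch = s$epoch, popularity = unname(s$weights))
  })
  edges <- purrr::map_dfr(seq_len(length(topic_sets) - 1L), function(i) {
    w <- pairwise_weights(topic_sets[[i]], topic_sets[[i + 1L]], metric)
    tibble(
      from = rep(rownames(w), times = ncol(w)),
      to = rep(colnames(w), each = nrow(w)),
      from_epoch = topic_sets[[i]]$epoch,
      to_epoch = topic_sets[[i + 1L]]$epoch,
      weight = as.vector(w)
    )
  })
  new_temporal_graph(nodes, edges, metric, pruned = FALSE)
}

#' Construct a temporal graph from node and edge tables
#'
#' Low-level constructor, mainly useful for building small graphs by hand
#' (e.g. worked examples of the event classifier). [build_full_graph()] is
#' the usual entry point.
#'
#' @param nodes Tibble with columns `node`, `epoch` (and optionally
#'   `popularity`, defaulting to uniform within epoch).
#' @param edges Tibble with columns `from`, `to` and optionally `weight`
#'   (default 0); `from_epoch`/`to_epoch` are filled from `nodes`.
#' @param metric Metric label for the graph.
#' @param pruned Whether the graph is to be treated as pruned.
#' @param zeta Operating point recorded on the graph, if any.
#' @return A `tf_temporal_graph`.
#' @export
temporal_graph <- function(nodes, edges, metric = "bhd", pruned = TRUE,
                           zeta = NA_real_) {
  nodes <- as_tibble(nodes)
  edges <- as_tibble(edges)
  if (!"popularity" %in% names(nodes)) {
    nodes <- nodes |>
      dplyr::group_by(.data$epoch) |>
      dplyr::mutate(popularity = 1 / dplyr::n()) |>
      dplyr::ungroup()
  }
  if (!"weight" %in% names(edges)) edges$weight <- 0
  lut <- setNames(nodes$epoch, nodes$node)
  edges$from_epoch <- unname(lut[edges$from])
  edges$to_epoch <- unname(lut[edges$to])
  if (anyNA(edges$from_epoch) || anyNA(edges$to_epoch)) {
    abort("Every edge endpoint must appear in `nodes`.")
  }
  if (any(edges$to_epoch != edges$from_epoch + 1L)) {
    abort("Edges must connect adjacent epochs (to_epoch == from_epoch + 1).")
  }
  new_temporal_graph(nodes, edges[c("from", "to", "from_epoch", "to_epoch", "weight")],
                     metric, pruned = pruned, zeta = zeta)
}

new_temporal_graph <- function(nodes, edges, metric, pruned, zeta = NA_real_,
                               threshold = NA_real_) {
  structure(
    list(nodes = nodes, edges = edges, metric = metric,
         pruned = pruned, zeta = zeta, threshold = threshold),
    class = "tf_temporal_graph"
  )
}

#' @export
print.tf_temporal_graph <- function(x, ...) {
  cat(sprintf("<tf_temporal_graph> metric %s: %d nodes over %d epochs, %d edges%s\n",
              x$metric, nrow(x$nodes), length(unique(x$nodes$epoch)), nrow(x$edges),
              if (x$pruned) sprintf(" (pruned at zeta = %.3g, threshold %.4g)",
                                    x$zeta, x$threshold) else " (full)"))
  invisible(x)
}

#' @export
tidy.tf_temporal_graph <- function(x, ...) {
  dplyr::mutate(x$edges, metric = x$metric, pruned = x$pruned)
}

#' Empirical-CDF weight threshold at operating point zeta
#'
#' Pools the weights of every inter-topic connection in the full graph
#' (all epoch pairs together), forms the empirical CDF, and returns the
#' order-statistics `(1 - zeta)`-quantile: the smallest weight `w` such
#' that at least a fraction `1 - zeta` of edges weigh at most `w`.
#' Infinite weights participate as the largest elements. Retaining edges
#' up to this threshold keeps the most-related `(1 - zeta)` fraction of
#' candidate connections, e.g. `zeta = 0.9` keeps the strongest 10%.
#'
#' @param graph A full (unpruned) `tf_temporal_graph`.
#' @param zeta Operating point in `[0, 1]`.
#' @return The weight threshold (scalar).
#' @export
cdf_threshold <- function(graph, zeta) {
  stopifnot(inherits(graph, "tf_temporal_graph"))
  if (graph$pruned) abort("`graph` must be the full (unpruned) graph.")
  if (!isTRUE(zeta >= 0 && zeta <= 1)) abort("`zeta` must be in [0, 1].")
  w <- graph$edges$weight
  if (length(w) == 0L) abort("Graph has no edges.")
  if (!any(is.finite(w))) abort("Graph has no finite-weight edges.")
  w <- sort(w)  # +Inf sorts last
  idx <- max(1L, ceiling((1 - zeta) * length(w)))
  w[idx]
}

#' Prune a full relatedness graph at operating point zeta
#'
#' Retains exactly the edges whose weight is at most
#' [cdf_threshold()]`(graph, zeta)`; ties at the threshold are all
#' retained, so the result is deterministic and order-independent. The
#' retained fraction is `1 - zeta` up to the tie mass at the threshold.
#'
#' @inheritParams cdf_threshold
#' @return A pruned `tf_temporal_graph` with the same node set.
#' @export
prune_graph <- function(graph, zeta) {
  thr <- cdf_threshold(graph, zeta)
  edges <- dplyr::filter(graph$edges, .data$weight <= thr)
  new_temporal_graph(graph$nodes, edges, graph$metric, pruned = TRUE,
                     zeta = zeta, threshold = thr)
}

node_degrees <- function(graph) {
  nodes <- graph$nodes
  outd <- dplyr::count(graph$edges, .data$from, name = "out_degree")
  ind <- dplyr::count(graph$edges, .data$to, name = "in_degree")
  nodes |>
    dplyr::left_join(outd, by = c(node = "from")) |>
    dplyr::left_join(ind, by = c(node = "to")) |>
    dplyr::mutate(out_degree = dplyr::coalesce(.data$out_degree, 0L),
                  in_degree = dplyr::coalesce(.data$in_degree, 0L))
}

#' Classify topic evolution events from the pruned relatedness graphs
#'
#' Reads the local structure of the three pruned graphs into the seven
#' event kinds. From the Bhattacharyya graph (gradual, similarity-based
#' phenomena):
#'
#' * **emerged** — a node with no incident (incoming) edge, in any epoch
#'   after the first;
#' * **vanished** — a node from which no edge originates, in any epoch
#'   before the last;
#' * **evolved** — exactly one edge originates from the node and it is the
#'   only edge incident to its target in the following epoch;
#' * **speciated** — two or more edges originate from the node (gradual
#'   differentiation of descendants from a common parent);
#' * **converged** — two or more edges are incident to the node.
#'
#' From the forward KLD graph: **split** — two or more edges originate
#' from a node. From the backward KLD graph: **merged** — two or more
#' edges incident to a node. Splitting and merging are abrupt support
#' partitions/unions that a symmetric overlap measure cannot see, which is
#' why they are read off the directed-divergence graphs. Events from
#' different metrics are not mutually exclusive; each event carries its
#' supporting metric.
#'
#' @param bhd,kld_f,kld_b Pruned `tf_temporal_graph`s over the same node
#'   set for the `"bhd"`, `"kld_forward"` and `"kld_backward"` metrics.
#' @return A tibble of events: `kind`, `metric`, `epoch` (the earlier
#'   epoch of the transition for parent-focused kinds, the node's epoch
#'   for emerged/vanished and child-focused kinds), `parents` and
#'   `children` (list-columns of node ids).
#' @export
classify_events <- function(bhd, kld_f, kld_b) {
  for (g in list(bhd, kld_f, kld_b)) stopifnot(inherits(g, "tf_temporal_graph"))
  key <- function(g) dplyr::arrange(g$nodes, .data$node)$node
  if (!identical(key(bhd), key(kld_f)) || !identical(key(bhd), key(kld_b))) {
    abort("The three graphs must share the same node set.")
  }
  first_epoch <- min(bhd$nodes$epoch)
  last_epoch <- max(bhd$nodes$epoch)
  deg <- node_degrees(bhd)

  ev <- list()
  emerged <- dplyr::filter(deg, .data$epoch > first_epoch, .data$in_degree == 0L)
  if (nrow(emerged)) {
    ev$emerged <- tibble(kind = "emerged", metric = "bhd", epoch = emerged$epoch,
                         parents = list_of_each(character(0), nrow(emerged)),
                         children = as.list(emerged$node))
  }
  vanished <- dplyr::filter(deg, .data$epoch < last_epoch, .data$out_degree == 0L)
  if (nrow(vanished)) {
    ev$vanished <- tibble(kind = "vanished", metric = "bhd", epoch = vanished$epoch,
                          parents = as.list(vanished$node),
                          children = list_of_each(character(0), nrow(vanished)))
  }
  # evolved: unique out-edge whose target has a unique in-edge
  ind <- dplyr::count(bhd$edges, .data$to, name = "in_degree")
  uniq_out <- dplyr::add_count(bhd$edges, .data$from, name = "out_degree") |>
    dplyr::filter(.data$out_degree == 1L) |>
    dplyr::left_join(ind, by = "to") |>
    dplyr::filter(.data$in_degree == 1L)
  if (nrow(uniq_out)) {
    ev$evolved <- tibble(kind = "evolved", metric = "bhd", epoch = uniq_out$from_epoch,
                         parents = as.list(uniq_out$from),
                         children = as.list(uniq_out$to))
  }
  ev$speciated <- branching_events(bhd, "speciated", "bhd")
  ev$converged <- joining_events(bhd, "converged", "bhd")
  ev$split <- branching_events(kld_f, "split", "kld_forward")
  ev$merged <- joining_events(kld_b, "merged", "kld_backward")

  out <- dplyr::bind_rows(ev)
  if (nrow(out) == 0L) {
    out <- tibble(kind = character(), metric = character(), epoch = integer(),
                  parents = list(), children = list())
  }
  dplyr::arrange(out, .data$epoch, .data$kind)
}

list_of_each <- function(x, n) rep(list(x), n)

# one parent, >=2 children (speciation under BHD, splitting under KLD-forward)
branching_events <- function(graph, kind, metric) {
  br <- graph$edges |>
    dplyr::group_by(.data$from, .data$from_epoch) |>
    dplyr::summarise(children = list(sort(.data$to)), n = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n >= 2L)
  if (nrow(br) == 0L) return(NULL)
  tibble(kind = kind, metric = metric, epoch = br$from_epoch,
         parents = as.list(br$from), children = br$children)
}

# >=2 parents, one child (convergence under BHD, merging under KLD-backward)
joining_events <- function(graph, kind, metric) {
  jn <- graph$edges |>
    dplyr::group_by(.data$to, .data$to_epoch) |>
    dplyr::summarise(parents = list(sort(.data$from)), n = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n >= 2L)
  if (nrow(jn) == 0L) return(NULL)
  tibble(kind = kind, metric = metric, epoch = jn$to_epoch,
         parents = jn$parents, children = as.list(jn$to))
}

#' Fraction of one graph's edges shared with another
#'
#' For an adjacent epoch pair, the number of connections present in both
#' pruned graphs divided by the number of connections in `g1` (edge
#' identity is the source/target topic pair; weights are ignored). This is
#' the cross-metric overlap statistic: a low value demonstrates that the
#' two relatedness measures capture different types of topic relatedness.
#'
#' @param g1,g2 Pruned `tf_temporal_graph`s over the same node set.
#' @param epoch The earlier epoch of the pair, or `NULL` (default) for a
#'   table over all pairs.
#' @return A scalar fraction when `epoch` is given (`NA` if `g1` has no
#'   edges in that pair), else a tibble `epoch`, `n_g1`, `n_shared`,
#'   `fraction`.
#' @export
shared_edge_fraction <- function(g1, g2, epoch = NULL) {
  stopifnot(inherits(g1, "tf_temporal_graph"), inherits(g2, "tf_temporal_graph"))
  if (!setequal(g1$nodes$node, g2$nodes$node)) {
    abort("Graphs must share the same node set.")
  }
  pairs <- sort(unique(g1$nodes$epoch))
  pairs <- pairs[-length(pairs)]
  res <- purrr::map_dfr(pairs, function(t) {
    e1 <- dplyr::filter(g1$edges, .data$from_epoch == t)
    e2 <- dplyr::filter(g2$edges, .data$from_epoch == t)
    n1 <- nrow(e1)
    shared <- nrow(dplyr::inner_join(e1[c("from", "to")], e2[c("from", "to")],
                                     by = c("from", "to")))
    tibble(epoch = t, n_g1 = n1, n_shared = shared,
           fraction = if (n1 > 0) shared / n1 else NA_real_)
  })
  if (is.null(epoch)) return(res)
  row <- dplyr::filter(res, .data$epoch == !!epoch)
  if (nrow(row) == 0L) abort(sprintf("No epoch pair starting at epoch %s.", epoch))
  row$fraction
}

#' Convert a temporal graph to igraph
#'
#' @param graph A `tf_temporal_graph`.
#' @return An `igraph` directed graph with `epoch`/`popularity` vertex
#'   attributes and `weight`/`metric` edge attributes.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "tf_temporal_graph"))
  ed <- graph$edges
  ed$metric <- graph$metric
  # GraphML cannot carry Inf weights; keep them as a flag attribute
  ed$finite <- is.finite(ed$weight)
  igraph::graph_from_data_frame(
    d = ed[c("from", "to", "weight", "metric", "finite")],
    directed = TRUE,
    vertices = graph$nodes
  )
}

#' Export a temporal graph as GraphML
#'
#' @param graph A `tf_temporal_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  g <- as_igraph(graph)
  w <- igraph::E(g)$weight
  w[!is.finite(w)] <- -1  # sentinel; `finite` edge attribute marks these
  igraph::E(g)$weight <- w
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export a temporal graph (with topic summaries) as viewer JSON
#'
#' Writes a JSON document with a `nodes` array (id, epoch, popularity and
#' the topic's top terms when topic sets are supplied) and an `edges`
#' array (source, target, metric, weight), consumable by an external
#' viewer.
#'
#' @param graph A `tf_temporal_graph`.
#' @param path Output path.
#' @param topic_sets Optional `tf_topic_sets` used to attach top terms.
#' @param n_terms Number of top terms per node.
#' @return `path`, invisibly.
#' @export
write_graph_json <- function(graph, path, topic_sets = NULL, n_terms = 8L) {
  nodes <- graph$nodes
  if (!is.null(topic_sets)) {
    terms <- purrr::map_dfr(topic_sets, tidy, n_terms = n_terms) |>
      dplyr::group_by(.data$topic) |>
      dplyr::summarise(top_terms = list(.data$term), .groups = "drop")
    nodes <- dplyr::left_join(nodes, terms, by = c(node = "topic"))
  }
  edges <- graph$edges
  edges$weight[!is.finite(edges$weight)] <- NA  # JSON has no Inf
  doc <- list(
    metric = graph$metric,
    pruned = graph$pruned,
    zeta = graph$zeta,
    threshold = if (is.finite(graph$threshold %||% NA)) graph$threshold else NULL,
    nodes = nodes,
    edges = edges
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Export classified events as CSV
#'
#' @param events Event tibble from [classify_events()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  flat <- dplyr::mutate(events,
                        parents = vapply(.data$parents, paste, "", collapse = ";"),
                        children = vapply(.data$children, paste, "", collapse = ";"))
  readr::write_csv(flat, path)
  invisible(path)
}
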
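make_sets <- function(Ks, V = 8, seed = 1) {
  set.seed(seed)
  purrr::map(seq_along(Ks), function(t) {
    tiny_topics(do.call(rbind, purrr::map(seq_len(Ks[t]), ~rand_simplex(V))), epoch = t)
  })
}

test_that("the full graph is complete bipartite between adjacent epochs", {
  sets <- make_sets(c(2, 3, 2))
  g <- build_full_graph(sets, "bhd")
  expect_equal(nrow(g$edges), 2 * 3 + 3 * 2)
  expect_false(g$pruned)
  expect_error(build_full_graph(sets[1], "bhd"), "two epochs")

  # weights match scalar metric recomputation edge by edge
  for (i in sample.int(nrow(g$edges), 5)) {
    e <- g$edges[i, ]
    p <- sets[[e$from_epoch]]$phi[e$from, ]
    q <- sets[[e$to_epoch]]$phi[e$to, ]
    expect_equal(e$weight, oracle_bhd(p, q), tolerance = 1e-10)
  }
})

test_that("the CDF threshold is the order-statistics quantile of pooled weights", {
  nodes <- tibble::tibble(node = c(paste0("a", 1:10), paste0("b", 1:10)),
                          epoch = rep(1:2, each = 10))
  edges <- tidyr::crossing(from = paste0("a", 1:10), to = paste0("b", 1:10))
  edges$weight <- seq(0.01, 1, length.out = 100)
  g100 <- temporal_graph(nodes, edges, pruned = FALSE)

  ten <- g100
  ten$edges <- ten$edges[1:10, ]
  ten$edges$weight <- seq(0.1, 1, by = 0.1)
  expect_equal(cdf_threshold(ten, 0.9), 0.1)
  expect_equal(cdf_threshold(ten, 0), 1.0)

  allc <- ten
  allc$edges$weight <- rep(0.42, 10)
  for (z in c(0, 0.3, 0.9)) expect_equal(cdf_threshold(allc, z), 0.42)

  none <- ten
  none$edges <- none$edges[0, ]
  expect_error(cdf_threshold(none, 0.5), "no edges")
  expect_error(cdf_threshold(ten, 1.2), "zeta")
})

test_that("pruning keeps exactly the most-related fraction with monotone nesting", {
  nodes <- tibble::tibble(node = c(paste0("a", 1:10), paste0("b", 1:10)),
                          epoch = rep(1:2, each = 10))
  edges <- tidyr::crossing(from = paste0("a", 1:10), to = paste0("b", 1:10))
  set.seed(7)
  edges$weight <- sample(seq(0.01, 1, length.out = 100))
  g <- temporal_graph(nodes, edges, pruned = FALSE)

  expect_equal(nrow(prune_graph(g, 0.5)$edges), 50L)
  expect_equal(nrow(prune_graph(g, 0.9)$edges), 10L)
  expect_equal(nrow(prune_graph(g, 0)$edges), 100L)

  edge_key <- function(p) paste(p$edges$from, p$edges$to)
  prev <- NULL
  for (z in rev(c(0, 0.25, 0.5, 0.75, 0.9))) {  # tightest first
    keys <- edge_key(prune_graph(g, z))
    if (!is.null(prev)) expect_true(all(prev %in% keys))
    prev <- keys
  }

  # ties at the threshold are all retained
  gt <- g
  gt$edges$weight <- rep(c(0.1, 0.9), each = 50)
  expect_equal(nrow(prune_graph(gt, 0.9)$edges), 50L)
})

test_that("infinite weights are prunable tail mass, never the threshold winner", {
  nodes <- tibble::tibble(node = c("a1", "a2", "b1", "b2"), epoch = c(1, 1, 2, 2))
  edges <- tibble::tibble(from = c("a1", "a1", "a2", "a2"),
                          to = c("b1", "b2", "b1", "b2"),
                          weight = c(0.1, 0.5, Inf, Inf))
  g <- temporal_graph(nodes, edges, pruned = FALSE)
  expect_equal(cdf_threshold(g, 0.5), 0.5)
  expect_equal(nrow(prune_graph(g, 0.5)$edges), 2L)
})

# A hand-built scenario covering all seven kinds:
# epochs 1..3; BHD graph: a1->b1 unique both sides (evolved); a2->{b2,b3}
# (speciated); {b2,b3}->c2 (converged); b4 has no incoming edge (emerged);
# a3 has no outgoing edge (vanished). KLD-forward: a3->{b4,b5} (split,
# with no BHD edges from a3: split without speciation). KLD-backward:
# {b1,b4}->c1 (merged).
seven_kind_graphs <- function() {
  nodes <- tibble::tibble(
    node = c("a1", "a2", "a3", "b1", "b2", "b3", "b4", "b5", "c1", "c2"),
    epoch = c(1, 1, 1, 2, 2, 2, 2, 2, 3, 3)
  )
  bhd <- temporal_graph(nodes, tibble::tibble(
    from = c("a1", "a2", "a2", "b2", "b3", "b1", "b5"),
    to   = c("b1", "b2", "b3", "c2", "c2", "c1", "c1")
  ), metric = "bhd")
  kld_f <- temporal_graph(nodes, tibble::tibble(
    from = c("a3", "a3"), to = c("b4", "b5")
  ), metric = "kld_forward")
  kld_b <- temporal_graph(nodes, tibble::tibble(
    from = c("b1", "b4"), to = c("c1", "c1")
  ), metric = "kld_backward")
  list(bhd = bhd, kld_f = kld_f, kld_b = kld_b, nodes = nodes)
}

test_that("the event classifier reproduces the hand-enumerated truth table", {
  gs <- seven_kind_graphs()
  ev <- classify_events(gs$bhd, gs$kld_f, gs$kld_b)

  pick <- function(kind) ev[ev$kind == kind, ]

  emerged <- pick("emerged")
  expect_setequal(unlist(emerged$children), c("b4", "b5"))
  expect_true(all(emerged$epoch == 2))
  # first-epoch nodes are never 'emerged' even with in-degree 0
  expect_false(any(unlist(pick("emerged")$children) %in% c("a1", "a2", "a3")))

  vanished <- pick("vanished")
  expect_setequal(unlist(vanished$parents), c("a3", "b4"))
  # last-epoch nodes are never 'vanished'
  expect_false(any(unlist(vanished$parents) %in% c("c1", "c2")))

  evolved <- pick("evolved")
  expect_equal(nrow(evolved), 1L)
  expect_equal(evolved$parents[[1]], "a1")
  expect_equal(evolved$children[[1]], "b1")

  speciated <- pick("speciated")
  expect_equal(nrow(speciated), 1L)
  expect_equal(speciated$parents[[1]], "a2")
  expect_equal(speciated$children[[1]], c("b2", "b3"))

  converged <- pick("converged")
  expect_equal(nrow(converged), 2L)  # c1 (from b1,b5) and c2 (from b2,b3)
  expect_setequal(unlist(converged$children), c("c1", "c2"))

  split <- pick("split")
  expect_equal(nrow(split), 1L)
  expect_equal(split$parents[[1]], "a3")
  expect_equal(split$children[[1]], c("b4", "b5"))
  # the split parent has no BHD out-edges: no speciation event for it
  expect_false("a3" %in% unlist(speciated$parents))

  merged <- pick("merged")
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$parents[[1]], c("b1", "b4"))
  expect_equal(merged$children[[1]], "c1")

  bad <- gs$kld_f
  bad$nodes <- bad$nodes[-1, ]
  expect_error(classify_events(gs$bhd, bad, gs$kld_b), "same node set")
})

test_that("every interior node is exactly emerged-or-linked and vanished-or-linked", {
  sets <- make_sets(c(4, 5, 4), seed = 3)
  g <- prune_graph(build_full_graph(sets, "bhd"), 0.6)
  ev <- classify_events(g, g, g)
  emerged <- unlist(ev$children[ev$kind == "emerged"])
  vanished <- unlist(ev$parents[ev$kind == "vanished"])
  for (n in g$nodes$node[g$nodes$epoch > 1]) {
    expect_equal(n %in% emerged, !n %in% g$edges$to)
  }
  for (n in g$nodes$node[g$nodes$epoch < 3]) {
    expect_equal(n %in% vanished, !n %in% g$edges$from)
  }
})

test_that("shared edge fraction counts common connections per epoch pair", {
  nodes <- tibble::tibble(node = c("a1", "a2", "b1", "b2"), epoch = c(1, 1, 2, 2))
  all4 <- tidyr::crossing(from = c("a1", "a2"), to = c("b1", "b2"))
  g1 <- temporal_graph(nodes, all4)
  expect_equal(shared_edge_fraction(g1, g1, epoch = 1), 1.0)

  g2 <- temporal_graph(nodes, all4[1, ])
  expect_equal(shared_edge_fraction(g2, g1, epoch = 1), 1.0)
  expect_equal(shared_edge_fraction(g1, g2, epoch = 1), 0.25)

  g3 <- temporal_graph(nodes, tibble::tibble(from = "a1", to = "b2"))
  g4 <- temporal_graph(nodes, tibble::tibble(from = "a2", to = "b1"))
  expect_equal(shared_edge_fraction(g3, g4, epoch = 1), 0.0)

  g0 <- temporal_graph(nodes, all4[0, ])
  expect_true(is.na(shared_edge_fraction(g0, g1, epoch = 1)))
})

test_that("graphs export to GraphML and viewer JSON", {
  sets <- make_sets(c(2, 2), seed = 5)
  g <- prune_graph(build_full_graph(sets, "bhd"), 0.5)

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g, gml)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(back), 4)
  expect_equal(igraph::ecount(back), nrow(g$edges))

  js <- withr::local_tempfile(fileext = ".json")
  write_graph_json(g, js, topic_sets = sets, n_terms = 3)
  doc <- jsonlite::read_json(js)
  expect_equal(doc$metric, "bhd")
  expect_length(doc$nodes, 4)
  expect_length(doc$nodes[[1]]$top_terms, 3)

  ev <- classify_events(g, g, g)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, csv)
  expect_true(file.exists(csv))
})
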
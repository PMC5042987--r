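split_spec <- function(n_children = 2L, block = 20L) {
  planted_dynamics_spec(
    tibble::tibble(name = "SP", block_size = block, behaviour = "stable",
                   from = 1L, to = 1L),
    tibble::tibble(kind = "split", epoch = 1L, parents = list("SP"),
                   children = list(paste0("c", seq_len(n_children)))),
    n_epochs = 2L, docs_per_epoch = 10L, doc_length = 10L, seed = 1L
  )
}

test_that("a hard split of a uniform parent yields the closed-form signatures", {
  truth <- make_planted_topics(split_spec())
  parent <- truth$topics[[1]]$phi["e1.SP", ]
  c1 <- truth$topics[[2]]$phi["e2.c1", ]
  c2 <- truth$topics[[2]]$phi["e2.c2", ]

  # children are uniform over 10 disjoint terms each
  expect_equal(sum(c1 > 0), 10)
  expect_equal(sum(c2 > 0), 10)
  expect_equal(sum(c1 > 0 & c2 > 0), 0)
  expect_equal(unique(round(c1[c1 > 0], 12)), 0.1)

  expect_equal(kld(c1, parent), log(2), tolerance = 1e-10)
  expect_equal(bhattacharyya(c1, parent), -log(10 * sqrt(0.005)), tolerance = 1e-10)
  # generator bookkeeping agrees with the metric oracle to the same precision
  expect_equal(truth$split_detail$retained_mass, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(kld(c2, parent), log(1 / truth$split_detail$retained_mass[2]),
               tolerance = 1e-10)
})

test_that("split signatures hold for drifted parents and more children", {
  spec <- planted_dynamics_spec(
    tibble::tibble(name = "SP", block_size = 21L, behaviour = "drift",
                   from = 1L, to = 2L),
    tibble::tibble(kind = "split", epoch = 2L, parents = list("SP"),
                   children = list(c("x", "y", "z"))),
    n_epochs = 3L, docs_per_epoch = 10L, doc_length = 10L, seed = 8L
  )
  truth <- make_planted_topics(spec)
  parent <- truth$topics[[2]]$phi["e2.SP", ]
  for (ch in c("x", "y", "z")) {
    child <- truth$topics[[3]]$phi[paste0("e3.", ch), ]
    m <- truth$split_detail$retained_mass[truth$split_detail$child == ch]
    expect_equal(kld(child, parent), log(1 / m), tolerance = 1e-10)
    expect_equal(bhattacharyya(child, parent), 0.5 * log(1 / m), tolerance = 1e-10)
  }
  expect_equal(sum(truth$split_detail$retained_mass), 1, tolerance = 1e-12)
})

test_that("stable topics persist identically; merges average disjoint parents", {
  spec <- planted_dynamics_spec(
    tibble::tibble(name = c("A", "M1", "M2"), block_size = c(6L, 10L, 10L),
                   behaviour = "stable", from = 1L, to = c(3L, 2L, 2L)),
    tibble::tibble(kind = "merge", epoch = 2L, parents = list(c("M1", "M2")),
                   children = list("M")),
    n_epochs = 3L, docs_per_epoch = 10L, doc_length = 10L, seed = 2L
  )
  truth <- make_planted_topics(spec)
  expect_equal(truth$topics[[1]]$phi["e1.A", ], truth$topics[[2]]$phi["e2.A", ])
  expect_equal(bhattacharyya(truth$topics[[1]]$phi["e1.A", ],
                             truth$topics[[2]]$phi["e2.A", ]), 0)

  merged <- truth$topics[[3]]$phi["e3.M", ]
  expect_equal(sum(merged > 0), 20)
  expect_equal(unique(round(merged[merged > 0], 12)), 0.05)
  # merged-topic KLD-backward signature: kld(parent, child) = ln 2
  expect_equal(kld(truth$topics[[2]]$phi["e2.M1", ], merged), log(2),
               tolerance = 1e-10)
})

test_that("all planted matrices stay row-stochastic through every transformation", {
  truth <- make_planted_topics(demo_dynamics_spec(seed = 6L))
  for (ts in truth$topics) {
    expect_true(all(ts$phi >= 0))
    expect_equal(rowSums(ts$phi), rep(1, nrow(ts$phi)), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  # the event log contains every scripted phenomenon
  expect_setequal(
    intersect(unique(truth$events$kind),
              c("split", "speciated", "merged", "converged", "emerged", "vanished")),
    c("split", "speciated", "merged", "converged", "emerged", "vanished")
  )
})

test_that("inconsistent scripts are rejected with the first violation named", {
  base <- tibble::tibble(name = "A", block_size = 10L, behaviour = "stable",
                         from = 1L, to = 1L)
  expect_error(planted_dynamics_spec(
    base, tibble::tibble(kind = "split", epoch = 1L, parents = list("NOPE"),
                         children = list(c("x", "y"))),
    n_epochs = 2L), "NOPE")
  expect_error(planted_dynamics_spec(
    base, tibble::tibble(kind = "split", epoch = 1L, parents = list("A"),
                         children = list("x")),
    n_epochs = 2L), "arity")
  expect_error(planted_dynamics_spec(
    base, tibble::tibble(kind = "merge", epoch = 1L, parents = list("A"),
                         children = list("A")),
    n_epochs = 2L), "collides|arity")
  expect_error(planted_dynamics_spec(
    tibble::tibble(name = c("A", "U"), block_size = c(10L, 0L),
                   behaviour = "stable", from = 1L, to = 1L,
                   span = list(NULL, "Z")),
    NULL, n_epochs = 1L), "unknown lineage")
})

test_that("document sampling is reproducible, complete and epoch-aligned", {
  spec <- tiny_pipeline_spec(seed = 19L)
  truth <- make_planted_topics(spec)
  docs1 <- sample_documents(truth)
  docs2 <- sample_documents(truth)
  expect_identical(docs1$text, docs2$text)
  expect_identical(docs1$date, docs2$date)

  expect_equal(nrow(docs1), 2L * spec$docs_per_epoch)
  expect_equal(sum(lengths(docs1$tokens)), nrow(docs1) * spec$doc_length)

  # timestamps fall inside their epoch's interval and re-partition recovers it
  ep <- partition_epochs(docs1, spec$epoch_length_days)
  joined <- dplyr::left_join(docs1[c("doc_id", "epoch")], ep$assignment, by = "doc_id")
  expect_equal(joined$epoch.x, joined$epoch.y)
})

test_that("long documents from one topic converge to that topic's law", {
  spec <- planted_dynamics_spec(
    tibble::tibble(name = "only", block_size = 30L, behaviour = "stable",
                   from = 1L, to = 1L),
    NULL, n_epochs = 1L, docs_per_epoch = 1L, doc_length = 10000L, seed = 29L
  )
  truth <- make_planted_topics(spec)
  docs <- sample_documents(truth)
  freq <- table(factor(docs$tokens[[1]], levels = truth$vocab)) / 10000
  tv <- 0.5 * sum(abs(as.numeric(freq) - truth$topics[[1]]$phi[1, ]))
  expect_lt(tv, 0.1)
})

test_that("topic recovery matching is exact under identity and permutation", {
  truth <- make_planted_topics(tiny_pipeline_spec(seed = 37L))
  m <- evaluate_topic_recovery(truth, truth$topics)
  expect_equal(m$fraction_matched, 1)
  expect_equal(max(m$matching$bhd), 0, tolerance = 1e-12)

  permuted <- purrr::map(truth$topics, function(ts) {
    idx <- rev(seq_len(nrow(ts$phi)))
    topic_set(ts$phi[idx, ], weights = ts$weights[idx], epoch = ts$epoch,
              vocab = ts$vocab, topic_ids = paste0("perm", idx))
  })
  m2 <- evaluate_topic_recovery(truth, permuted)
  expect_equal(m2$fraction_matched, 1)
  expect_equal(max(m2$matching$bhd), 0, tolerance = 1e-12)

  # mild noise still beats random pairings on average
  set.seed(41)
  noisy <- purrr::map(truth$topics, function(ts) {
    phi <- ts$phi + matrix(rgamma(length(ts$phi), 0.05), nrow(ts$phi))
    topic_set(phi / rowSums(phi), epoch = ts$epoch, vocab = ts$vocab)
  })
  m3 <- evaluate_topic_recovery(truth, noisy, threshold = 0.5)
  random_bhd <- bhattacharyya(truth$topics[[1]]$phi[1, ], noisy[[1]]$phi[2, ])
  expect_lt(m3$mean_bhd, random_bhd)
})

test_that("event recovery scores detections against the planted log", {
  truth <- make_planted_topics(split_spec())
  # detections expressed in inferred ids = planted ids (identity matching)
  ident <- structure(list(matching = dplyr::mutate(
    truth$lineages, lineage = .data$lineage, planted_id = .data$topic_id,
    inferred_id = .data$topic_id, bhd = 0, matched = TRUE
  ), threshold = 0.2, fraction_matched = 1, mean_bhd = 0), class = "tf_matching")

  detected <- tibble::tibble(
    kind = "split", metric = "kld_forward", epoch = 2L,
    parents = list("e2.SP"), children = list(c("e3.c1", "e3.c2"))
  )
  # (the split in this spec happens at transition 1: epoch must match)
  detected$epoch <- 1L
  detected$parents <- list("e1.SP")
  detected$children <- list(c("e2.c1", "e2.c2"))
  res <- evaluate_event_recovery(truth, detected, ident)
  split_row <- res[res$kind == "split", ]
  expect_equal(split_row$precision, 1)
  expect_equal(split_row$recall, 1)

  none <- detected[0, ]
  res0 <- evaluate_event_recovery(truth, none, ident)
  expect_equal(res0$recall[res0$kind == "split"], 0)
  expect_true(is.na(res0$precision[res0$kind == "split"]))

  spurious <- dplyr::bind_rows(detected, tibble::tibble(
    kind = "split", metric = "kld_forward", epoch = 1L,
    parents = list("e1.SP"), children = list(c("e2.c2", "e2.c1", "extra"))
  ))
  res1 <- evaluate_event_recovery(truth, spurious, ident)
  expect_equal(res1$precision[res1$kind == "split"], 1 / 2)
})

test_that("the ground-truth bundle and corpus serialize to plain text", {
  syn <- synth_corpus(tiny_pipeline_spec(seed = 43L))
  dir <- withr::local_tempdir()
  write_ground_truth(syn$truth, dir)
  expect_true(file.exists(file.path(dir, "true_events.csv")))
  expect_true(file.exists(file.path(dir, "topics_epoch002.csv")))
  jsonl <- file.path(dir, "corpus.jsonl")
  write_corpus(syn$docs, jsonl)
  expect_equal(nrow(read_corpus(jsonl)), nrow(syn$docs))
})
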
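# shared fixtures built in code

# a tiny corpus tibble with one document per given day offset
day_corpus <- function(days, origin = as.Date("2020-01-01")) {
  tibble::tibble(
    doc_id = sprintf("d%02d", seq_along(days)),
    date = origin + days - 1L,
    text = sprintf("doc number %d", seq_along(days))
  )
}

# random point on the V-simplex (strictly positive unless zeros requested)
rand_simplex <- function(V, zeros = 0L) {
  x <- rgamma(V, 1)
  if (zeros > 0L) x[sample.int(V, zeros)] <- 0
  if (sum(x) == 0) x[1L] <- 1
  x / sum(x)
}

# brute-force scalar oracles, written independently of the package's
# vectorized implementations
oracle_bhd <- function(p, q) {
  s <- 0
  for (i in seq_along(p)) s <- s + sqrt(p[i] * q[i])
  if (s == 0) Inf else -log(s)
}

oracle_kld <- function(p, q) {
  s <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) {
      if (q[i] == 0) return(Inf)
      s <- s + p[i] * log(p[i] / q[i])
    }
  }
  s
}

# topic set with given phi rows
tiny_topics <- function(phi, epoch, ids = NULL) {
  topic_set(phi, epoch = epoch, topic_ids = ids)
}

# a small two-epoch, two-stable-topic corpus spec for fast pipeline tests
tiny_pipeline_spec <- function(seed = 5L) {
  planted_dynamics_spec(
    tibble::tibble(name = c("A", "B"), block_size = c(10L, 10L),
                   behaviour = "stable", from = 1L, to = 2L),
    NULL, n_epochs = 2L, docs_per_epoch = 60L, doc_length = 25L,
    epoch_length_days = 50L, seed = seed
  )
}

fast_control <- function(...) {
  hdp_control(max_iters = 200L, burn_in = 100L, ...)
}
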
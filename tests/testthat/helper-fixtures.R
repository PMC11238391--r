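# Shared fixtures and independent oracles.

# Build a trace directly from a label sequence.
make_trace <- function(labels, ids = sprintf("r%03d", seq_along(labels)), ...) {
  screening_trace(ordered_ids = ids, labels_in_order = labels, ...)
}

# Random trace of pool size n with r relevant records.
random_trace <- function(n, r) {
  make_trace(sample(c(rep(1L, r), rep(0L, n - r))))
}

# Brute-force metric oracles: recount everything from the raw label sequence,
# sharing no code with the package implementations.
oracle_wss <- function(labels, r = 0.95) {
  n <- length(labels)
  total_rel <- sum(labels)
  need <- ceiling(r * total_rel)
  found <- 0L
  n_star <- n
  for (k in seq_len(n)) {
    found <- found + labels[k]
    if (found >= need) { n_star <- k; break }
  }
  100 * ((n - n_star) / n - (1 - r))
}

oracle_rrf <- function(labels, p = 0.10) {
  k <- ceiling(p * length(labels))
  100 * sum(labels[seq_len(k)]) / sum(labels)
}

oracle_recall <- function(labels) {
  out <- integer(length(labels))
  acc <- 0L
  for (k in seq_along(labels)) {
    acc <- acc + labels[k]
    out[k] <- acc
  }
  out
}

# Small in-memory CSV corpus fixture.
write_fixture_csv <- function(path,
                              ids = c("a", "b", "c"),
                              titles = c("Alpha trial", "Beta cohort", "Gamma review"),
                              abstracts = c("randomized alpha", "observational beta",
                                            "systematic gamma"),
                              fulltext = c("1", "0", "")) {
  writeLines(c("record_id,title,abstract,label_fulltext",
               paste(ids, titles, abstracts, fulltext, sep = ",")),
             path)
  path
}

# Tiny perfectly separable corpus built by hand (not via the generator).
toy_separable_corpus <- function(n_rel = 4, n_irr = 16) {
  rel_text <- replicate(n_rel, paste(sample(c("aa", "bb", "cc"), 8, TRUE), collapse = " "))
  irr_text <- replicate(n_irr, paste(sample(c("xx", "yy", "zz"), 8, TRUE), collapse = " "))
  corpus(data.frame(
    record_id = sprintf("t%02d", seq_len(n_rel + n_irr)),
    title = sprintf("title %02d", seq_len(n_rel + n_irr)),
    abstract = c(rel_text, irr_text),
    label_fulltext = c(rep(1L, n_rel), rep(0L, n_irr))))
}
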
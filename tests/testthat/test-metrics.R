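test_that("recall curve is the running count of relevant records", {
  expect_equal(recall_curve(make_trace(c(1, 0, 1))), c(1, 1, 2))
  expect_equal(recall_curve(make_trace(rep(1, 4))), 1:4)
  set.seed(1)
  for (i in 1:25) {
    tr <- random_trace(sample(5:50, 1), sample(1:4, 1))
    curve <- recall_curve(tr)
    expect_equal(curve, oracle_recall(tr$labels_in_order))
    expect_true(all(diff(curve) >= 0))
    expect_equal(curve[tr$n_pool], tr$r_pool)
  }
})

test_that("wss hits its closed-form best and worst cases", {
  best <- make_trace(rep(c(1L, 0L), c(10, 90)))
  expect_equal(wss(best), 85)                       # 100 * (0.95 - 10/100)
  worst <- make_trace(rep(c(0L, 1L), c(90, 10)))
  expect_equal(wss(worst), -5)
  # recall target uses the ceiling: 95% of 5 relevant means all 5
  five <- make_trace(c(rep(0L, 15), 1L, 1L, 1L, 1L, rep(0L, 80), 1L))
  expect_equal(wss(five), 100 * ((100 - 100) / 100 - 0.05))
})

test_that("wss and rrf agree with brute-force recomputation on random small instances", {
  set.seed(77)
  for (i in 1:200) {
    n <- sample(10:50, 1)
    r <- sample(seq_len(max(1, n %/% 3)), 1)
    tr <- random_trace(n, r)
    expect_equal(wss(tr), oracle_wss(tr$labels_in_order))
    expect_equal(rrf(tr), oracle_rrf(tr$labels_in_order))
  }
})

test_that("wss is antitone in n* and rrf isotone in the prefix count", {
  n <- 40
  wss_by_nstar <- vapply(5:n, function(k) {
    labels <- rep(0L, n)
    labels[c(1:4, k)] <- 1L   # 5 relevant, last one found at position k
    wss(make_trace(labels))
  }, 0)
  expect_true(all(diff(wss_by_nstar) < 0))
  rrf_by_prefix <- vapply(0:4, function(j) {
    labels <- rep(0L, n)
    if (j > 0) labels[seq_len(j)] <- 1L
    labels[(n - 4 + j):n] <- 1L
    rrf(make_trace(labels))
  }, 0)
  expect_true(all(diff(rrf_by_prefix) > 0))
})

test_that("time to discovery is position over pool size, priors absent", {
  labels <- rep(0L, 200); labels[30] <- 1L
  td <- time_to_discovery(make_trace(labels))
  expect_equal(unname(td), 0.15)
  expect_equal(names(td), "r030")
  first <- time_to_discovery(make_trace(c(1L, rep(0L, 9))))
  expect_equal(unname(first), 1 / 10)
  # prior relevant records never enter the pool, hence never the TD map
  cx <- toy_separable_corpus(n_rel = 4, n_irr = 16)
  prior <- select_priors(cx, "fulltext", seed = 1)
  tr <- simulate_screening(cx, "fulltext", prior)
  expect_false(prior$relevant_id %in% names(time_to_discovery(tr)))
})

test_that("atd pools TD values over records and runs", {
  t1 <- make_trace(c(0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L))  # TD 0.2
  t2 <- make_trace(c(0L, 0L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L))  # TD 0.6
  out <- atd(list(t1, t2))
  expect_equal(out$fraction, 0.4)
  expect_equal(out$abstracts, 0.4 * 10)
  expect_equal(out$n_discoveries, 2L)
  # concatenation oracle on multi-relevant traces
  t3 <- make_trace(c(1L, 0L, 1L, 0L))
  pooled <- atd(list(t1, t3))
  expect_equal(pooled$fraction,
               mean(c(time_to_discovery(t1), time_to_discovery(t3))))
  expect_error(atd(make_trace(rep(0L, 5))), class = "screensim_validation_error")
})

test_that("hard_to_find ranks by mean TD descending with deterministic ties and clamping", {
  t1 <- screening_trace(c("x", "y", "z", "w"), c(0L, 1L, 0L, 1L))  # y .5, w 1
  t2 <- screening_trace(c("y", "x", "w", "z"), c(1L, 0L, 1L, 0L))  # y .25, w .75
  out <- hard_to_find(list(t1, t2), top_k = 10)
  expect_equal(out$record_id, c("w", "y"))
  expect_equal(out$mean_td, c(mean(c(1, 0.75)), mean(c(0.5, 0.25))))
  expect_equal(out$n_runs, c(2L, 2L))
  expect_equal(nrow(hard_to_find(list(t1, t2), top_k = 1)), 1L)
  expect_error(hard_to_find(list(t1), top_k = 0), class = "screensim_config_error")
  # tie on mean TD breaks by record id
  t3 <- screening_trace(c("b", "a", "c", "d"), c(1L, 1L, 0L, 0L))
  expect_equal(hard_to_find(t3)$record_id[1:2], c("a", "b"))
})

test_that("a deliberately mislabeled relevant record ranks as hardest to find", {
  set.seed(14)
  hits <- 0L
  n_seeds <- 10L
  for (i in seq_len(n_seeds)) {
    cx <- generate_corpus(generator_config(seed = 400 + i, n_records = 120,
                                           prevalence = 0.1, signal_strength = 1,
                                           rater_fp = 0, rater_fn = 0,
                                           methodologist_exclusion = 0,
                                           fulltext_exclusion = 0))
    rec <- cx$records
    # flip one irrelevant record to "relevant": its text comes from the
    # irrelevant vocabulary, so the model has no way to surface it early
    victim <- which(rec$truth == 0L)[1L]
    rec$label_fulltext[victim] <- 1L
    noisy <- corpus(rec)
    traces <- run_batch(noisy, "fulltext", simulation_config(seed = i), n_runs = 3)
    top <- hard_to_find(traces, top_k = 1)$record_id
    if (top == rec$record_id[victim]) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("summarize_traces aggregates per-run metrics as mean and SD over runs", {
  t1 <- make_trace(rep(c(1L, 0L), c(5, 45)))
  t2 <- make_trace(rep(c(0L, 1L, 0L), c(10, 5, 35)))
  s <- summarize_traces(list(t1, t2))
  w <- c(wss(t1), wss(t2))
  expect_equal(s$wss$mean, mean(w))
  expect_equal(s$wss$sd, sd(w))
  expect_equal(s$n_runs, 2L)
})
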
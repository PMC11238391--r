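test_that("naive Bayes scores match an independent dense posterior computation", {
  texts <- c(p_rel = "aa aa aa", p_irr = "bb bb bb",
             cand_rel = "aa aa aa", cand_irr = "bb bb bb", cand_mid = "aa bb")
  f <- fit_features(texts)
  cfg <- simulation_config(smoothing = 1, balance_ratio = 1)
  s <- train_and_score(f, c("p_rel", "p_irr"), c(1, 0), cfg,
                       c("cand_rel", "cand_irr", "cand_mid"))
  expect_gt(s[["cand_rel"]], s[["cand_mid"]])
  expect_gt(s[["cand_mid"]], s[["cand_irr"]])
  # independent computation from the dense feature rows
  x <- as.matrix(f$matrix)
  theta1 <- (x["p_rel", ] + 1) / sum(x["p_rel", ] + 1)
  theta0 <- (x["p_irr", ] + 1) / sum(x["p_irr", ] + 1)
  logit <- x["cand_mid", ] %*% (log(theta1) - log(theta0))
  expect_equal(s[["cand_mid"]], plogis(as.numeric(logit)), tolerance = 1e-12)
})

test_that("identical feature rows get identical scores and empty candidate sets an empty vector", {
  texts <- c(a = "aa bb", b = "cc dd", c = "aa bb", d = "aa bb")
  f <- fit_features(texts)
  s <- train_and_score(f, c("a", "b"), c(1, 0), candidate_ids = c("c", "d"))
  expect_equal(s[["c"]], s[["d"]])
  expect_length(train_and_score(f, c("a", "b"), c(1, 0),
                                candidate_ids = character(0)), 0L)
  expect_error(train_and_score(f, c("a", "c"), c(1, 1), candidate_ids = "b"),
               class = "screensim_validation_error")
})

test_that("prior selection enforces the 1-relevant + 10-irrelevant contract", {
  cx <- toy_separable_corpus(n_rel = 5, n_irr = 16)
  p <- select_priors(cx, "fulltext", seed = 3)
  expect_s3_class(p, "prior_set")
  expect_length(p$relevant_id, 1L)
  expect_length(p$irrelevant_ids, 10L)
  labs <- stage_labels(cx, "fulltext")
  expect_equal(unname(labs[p$relevant_id]), 1L)
  expect_true(all(labs[p$irrelevant_ids] == 0L))
  expect_false(p$relevant_id %in% p$irrelevant_ids)

  one_rel <- toy_separable_corpus(n_rel = 1, n_irr = 16)
  expect_error(select_priors(one_rel, "fulltext"),
               "at least 2 relevant", class = "screensim_infeasible_error")
  few_irr <- toy_separable_corpus(n_rel = 3, n_irr = 9)
  expect_error(select_priors(few_irr, "fulltext"),
               "at least 10 irrelevant", class = "screensim_infeasible_error")
})

test_that("on a separable noise-free corpus every relevant record is screened first", {
  set.seed(5)
  cx <- generate_corpus(generator_config(seed = 5, n_records = 80,
                                         prevalence = 0.15, signal_strength = 1,
                                         rater_fp = 0, rater_fn = 0,
                                         methodologist_exclusion = 0,
                                         fulltext_exclusion = 0))
  prior <- select_priors(cx, "fulltext", seed = 1)
  tr <- simulate_screening(cx, "fulltext", prior)
  # oracle: sorting labels descending is the best achievable order
  expect_equal(tr$labels_in_order[seq_len(tr$r_pool)], rep(1L, tr$r_pool))
})

test_that("traces are reproducible permutations of the non-prior pool", {
  cx <- generate_corpus(generator_config(seed = 8, n_records = 60,
                                         prevalence = 0.2))
  prior <- select_priors(cx, "truth", seed = 2)
  cfg <- simulation_config(seed = 4)
  t1 <- simulate_screening(cx, "truth", prior, cfg)
  t2 <- simulate_screening(cx, "truth", prior, cfg)
  expect_identical(t1$ordered_ids, t2$ordered_ids)
  expect_setequal(t1$ordered_ids,
                  setdiff(record_ids(cx), c(prior$relevant_id, prior$irrelevant_ids)))
  expect_equal(t1$r_pool, sum(t1$labels_in_order))
})

test_that("with identical record text the trace equals the seeded shuffle (tie-break contract)", {
  n <- 30
  cx <- corpus(data.frame(record_id = sprintf("r%02d", 1:n),
                          title = sprintf("t%02d", 1:n),
                          abstract = "same words everywhere",
                          label_fulltext = rep(c(1L, 0L), c(5, n - 5))))
  prior <- select_priors(cx, "fulltext", seed = 1)
  cfg <- simulation_config(seed = 9)
  tr <- simulate_screening(cx, "fulltext", prior, cfg)
  pool <- setdiff(record_ids(cx), c(prior$relevant_id, prior$irrelevant_ids))
  shuffled <- withr::with_seed(
    screensim:::derive_seed(cfg$seed, "shuffle", prior$relevant_id),
    sample(pool))
  expect_identical(tr$ordered_ids, shuffled)
})

test_that("run_batch varies the relevant prior, shares irrelevant priors, and clamps n_runs", {
  cx <- toy_separable_corpus(n_rel = 5, n_irr = 20)
  traces <- run_batch(cx, "fulltext", simulation_config(seed = 6), n_runs = "all")
  expect_length(traces, 5L)
  rel_priors <- vapply(traces, function(t) t$prior$relevant_id, "")
  expect_length(unique(rel_priors), 5L)
  irr <- lapply(traces, function(t) t$prior$irrelevant_ids)
  for (i in 2:5) expect_identical(irr[[i]], irr[[1]])
  expect_equal(vapply(traces, `[[`, 0L, "run_index"), 1:5)
  expect_length(run_batch(cx, "fulltext", simulation_config(seed = 6), n_runs = 1), 1L)
  expect_warning(
    traces2 <- run_batch(cx, "fulltext", simulation_config(seed = 6), n_runs = 9),
    "clamped")
  expect_length(traces2, 5L)
})

test_that("the random scorer reproduces the random-reading order statistics", {
  cx <- generate_corpus(generator_config(seed = 31, n_records = 60,
                                         prevalence = 0.15, signal_strength = 1))
  cfg_r <- simulation_config(seed = 1, scorer = "random")
  wss_vals <- vapply(1:200, function(i) {
    cfg_i <- simulation_config(seed = i, scorer = "random")
    prior <- select_priors(cx, "truth", seed = i)
    wss(simulate_screening(cx, "truth", prior, cfg_i))
  }, 0)
  tr <- simulate_screening(cx, "truth", select_priors(cx, "truth", seed = 1), cfg_r)
  n <- tr$n_pool; r <- tr$r_pool
  m <- ceiling(0.95 * r)
  expected <- 100 * (1 - (m * (n + 1) / (r + 1)) / n - 0.05)
  se <- sd(wss_vals) / sqrt(length(wss_vals))
  expect_lt(abs(mean(wss_vals) - expected), 4 * se + 0.5)
})
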
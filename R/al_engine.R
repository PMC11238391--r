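#' Simulation configuration
#'
#' Parameters of the active-learning screening simulation.
#'
#' @param stage Label column playing ground truth: `"clinician"`,
#'   `"methodologist"` or `"fulltext"` (or any label column name).
#' @param smoothing Additive (Lidstone) smoothing constant of the multinomial
#'   naive Bayes classifier; default 3.822, the documented default of the
#'   screening tool family this simulation emulates.
#' @param balance_ratio Target ratio of total relevant to irrelevant training
#'   weight. Relevant records are dynamically up-weighted by
#'   `balance_ratio * n_irrelevant / n_relevant`, so the effective class
#'   masses stay at `balance_ratio : 1` however rare inclusions are.
#' @param retrain_every Retrain cadence: the classifier is refit after every
#'   `retrain_every` revealed labels (default 1); between refits the stale
#'   ranking is consumed top-down.
#' @param seed Master RNG seed; every random choice (prior draw, tie-break
#'   shuffle, random scorer) derives from it.
#' @param n_prior_irrelevant Number of irrelevant prior records (default 10).
#' @param scorer `"nb"` (trained classifier) or `"random"` (uniform-random
#'   relevance scores, the random-reading baseline).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(stage = "fulltext", smoothing = 3.822,
                              balance_ratio = 1, retrain_every = 1L,
                              seed = 1L, n_prior_irrelevant = 10L,
                              scorer = c("nb", "random")) {
  scorer <- match.arg(scorer)
  if (!is_scalar_number(smoothing) || smoothing <= 0) {
    abort_config("`smoothing` must be a positive number")
  }
  if (!is_scalar_number(balance_ratio) || balance_ratio <= 0) {
    abort_config("`balance_ratio` must be a positive number")
  }
  if (!is_scalar_number(retrain_every) || retrain_every < 1) {
    abort_config("`retrain_every` must be a positive integer")
  }
  structure(list(stage = stage, smoothing = smoothing,
                 balance_ratio = balance_ratio,
                 retrain_every = as.integer(retrain_every),
                 seed = as.integer(seed),
                 n_prior_irrelevant = as.integer(n_prior_irrelevant),
                 scorer = scorer),
            class = "simulation_config")
}

# Weighted multinomial NB sufficient statistics -> log-odds scoring weights.
# Per-class uniform sample weights cancel in the per-class term distributions,
# so only the class prior carries the balance ratio.
nb_weights <- function(c1, c0, n1, n0, smoothing, balance_ratio) {
  t1 <- c1 + smoothing
  t0 <- c0 + smoothing
  list(delta = log(t1 / sum(t1)) - log(t0 / sum(t0)),
       intercept = log(balance_ratio))
}

#' Train the ranker and score candidate records
#'
#' Fits a multinomial naive Bayes classifier with additive smoothing on the
#' TF-IDF rows of the training records (relevant records up-weighted per
#' `balance_ratio`) and returns the posterior probability of relevance for
#' each candidate. Deterministic given its inputs.
#'
#' @param features A [fit_features()] object covering all ids involved.
#' @param training_ids,training_labels Parallel vectors: record ids and their
#'   0/1 labels; both classes must be present.
#' @param config A [simulation_config()].
#' @param candidate_ids Record ids to score.
#' @return Named numeric vector of posterior relevance scores in (0, 1).
#' @export
train_and_score <- function(features, training_ids, training_labels,
                            config = simulation_config(), candidate_ids) {
  stopifnot(inherits(features, "tfidf_features"))
  x <- features$matrix
  missing <- setdiff(c(training_ids, candidate_ids), rownames(x))
  if (length(missing)) {
    abort_config(sprintf("ids not in feature matrix: %s",
                         paste(head(missing, 3L), collapse = ", ")))
  }
  training_labels <- coerce_label(training_labels, "training_labels")
  if (length(training_labels) != length(training_ids) || anyNA(training_labels)) {
    abort_validation("training labels must be 0/1 and parallel to training_ids")
  }
  if (length(unique(training_labels)) < 2L) {
    abort_validation("training set must contain both classes")
  }
  rel <- training_ids[training_labels == 1L]
  irr <- training_ids[training_labels == 0L]
  w <- nb_weights(
    c1 = colSums(x[rel, , drop = FALSE]),
    c0 = colSums(x[irr, , drop = FALSE]),
    n1 = length(rel), n0 = length(irr),
    smoothing = config$smoothing, balance_ratio = config$balance_ratio)
  if (!length(candidate_ids)) return(setNames(numeric(0), character(0)))
  s <- as.numeric(x[candidate_ids, , drop = FALSE] %*% w$delta) + w$intercept
  setNames(plogis(s), candidate_ids)
}

#' Select prior knowledge for a simulation
#'
#' Draws the seeded training knowledge: one relevant record plus
#' `n_irrelevant` irrelevant records at the given stage. The irrelevant set
#' is drawn once per (corpus, seed) and is meant to be shared across runs;
#' the relevant prior varies by run (see [run_batch()]).
#'
#' @param x A [corpus()].
#' @param stage Stage name or label column (see [stage_labels()]).
#' @param seed Integer seed for the draws.
#' @param relevant_id Optional explicit relevant prior; drawn from the seed
#'   when `NULL`.
#' @param n_irrelevant Number of irrelevant priors (default 10).
#' @return A `prior_set`: list with `relevant_id`, `irrelevant_ids`, `seed`.
#' @export
select_priors <- function(x, stage, seed = 1L, relevant_id = NULL,
                          n_irrelevant = 10L) {
  labels <- stage_labels(x, stage)
  rel_ids <- names(labels)[!is.na(labels) & labels == 1L]
  irr_ids <- names(labels)[!is.na(labels) & labels == 0L]
  if (length(rel_ids) < 2L) {
    abort_infeasible(sprintf(
      "simulation needs at least 2 relevant records at stage '%s' (1 as training data and 1 as a target to detect); found %d",
      stage, length(rel_ids)))
  }
  if (length(irr_ids) < n_irrelevant) {
    abort_infeasible(sprintf(
      "simulation needs at least %d irrelevant records at stage '%s'; found %d",
      n_irrelevant, stage, length(irr_ids)))
  }
  irrelevant_ids <- withr::with_seed(
    derive_seed(seed, "irrelevant-priors"),
    sample(irr_ids, n_irrelevant))
  if (is.null(relevant_id)) {
    relevant_id <- withr::with_seed(
      derive_seed(seed, "relevant-prior"),
      sample(rel_ids, 1L))
  } else if (!relevant_id %in% rel_ids) {
    abort_validation(sprintf("record '%s' is not relevant at stage '%s'",
                             relevant_id, stage))
  }
  structure(list(relevant_id = relevant_id,
                 irrelevant_ids = irrelevant_ids,
                 seed = as.integer(seed)),
            class = "prior_set")
}

#' Construct a screening trace
#'
#' The object every metric consumes: the order in which the non-prior pool
#' was screened together with the true labels revealed along the way.
#' [simulate_screening()] produces these; building one directly is useful for
#' baselines (e.g. a random permutation).
#'
#' @param ordered_ids Record ids in screening order (the whole pool).
#' @param labels_in_order Parallel 0/1 vector of true stage labels.
#' @param prior Optional `prior_set` that seeded the run.
#' @param run_index Integer run identifier.
#' @param stage Stage name the labels came from.
#' @return A `screening_trace`: list with `ordered_ids`, `labels_in_order`,
#'   `n_pool`, `r_pool`, `prior`, `run_index`, `stage`.
#' @export
screening_trace <- function(ordered_ids, labels_in_order, prior = NULL,
                            run_index = NA_integer_, stage = NA_character_) {
  labels_in_order <- coerce_label(labels_in_order, "labels_in_order")
  if (length(ordered_ids) != length(labels_in_order) || anyNA(labels_in_order)) {
    abort_validation("labels_in_order must be 0/1 and parallel to ordered_ids")
  }
  if (anyDuplicated(ordered_ids)) {
    abort_validation("ordered_ids must not contain duplicates")
  }
  structure(list(ordered_ids = as.character(ordered_ids),
                 labels_in_order = labels_in_order,
                 n_pool = length(ordered_ids),
                 r_pool = sum(labels_in_order),
                 prior = prior,
                 run_index = as.integer(run_index),
                 stage = stage),
            class = "screening_trace")
}

#' @export
print.screening_trace <- function(x, ...) {
  cat(sprintf("<screening_trace> run %s, stage %s: pool %d, relevant %d\n",
              x$run_index, x$stage, x$n_pool, x$r_pool))
  invisible(x)
}

#' Simulate one prioritized screening run
#'
#' Emulates a screener working through the pool with model support: starting
#' from the prior knowledge, the classifier is trained on all labels revealed
#' so far, the unscreened pool is scored, the top-scoring record is screened
#' next (its true stage label revealed), and the model is refit every
#' `retrain_every` labels — until the pool is exhausted. There is no stopping
#' rule: the metrics need the complete ordering. Ties in score are broken by
#' an initial seeded shuffle of the pool (lowest post-shuffle index wins), so
#' the whole trace is reproducible from (corpus, prior, config).
#'
#' @param x A [corpus()].
#' @param stage Stage name or label column providing ground truth.
#' @param prior A [select_priors()] result.
#' @param config A [simulation_config()].
#' @param features Optional precomputed [fit_features()] on the full corpus;
#'   computed on demand otherwise. Must cover every record.
#' @param run_index Integer recorded on the trace.
#' @return A [screening_trace()]; priors are excluded from the pool.
#' @export
simulate_screening <- function(x, stage, prior, config = simulation_config(),
                               features = NULL, run_index = 1L) {
  stopifnot(inherits(x, "corpus"), inherits(prior, "prior_set"))
  labels <- stage_labels(x, stage)
  prior_ids <- c(prior$relevant_id, prior$irrelevant_ids)
  bad <- setdiff(prior_ids, names(labels))
  if (length(bad)) {
    abort_validation(sprintf("prior ids not in corpus: %s",
                             paste(bad, collapse = ", ")))
  }
  if (labels[[prior$relevant_id]] != 1L ||
      any(labels[prior$irrelevant_ids] != 0L, na.rm = FALSE)) {
    abort_validation("prior labels disagree with the stage labels")
  }
  pool_ids <- setdiff(names(labels), prior_ids)
  if (anyNA(labels[pool_ids])) {
    abort_validation(sprintf("%d pool record(s) have missing labels at stage '%s'",
                             sum(is.na(labels[pool_ids])), stage))
  }
  if (is.null(features)) {
    features <- fit_features(record_texts(x))
  }
  # tie-break contract: one seeded shuffle, argmax takes the first maximum
  pool_ids <- withr::with_seed(
    derive_seed(config$seed, "shuffle", prior$relevant_id),
    sample(pool_ids))
  xp <- features$matrix[pool_ids, , drop = FALSE]
  n_pool <- length(pool_ids)

  c1 <- colSums(features$matrix[prior$relevant_id, , drop = FALSE])
  c0 <- colSums(features$matrix[prior$irrelevant_ids, , drop = FALSE])
  n1 <- 1L
  n0 <- length(prior$irrelevant_ids)

  active <- rep(TRUE, n_pool)
  scores <- rep(-Inf, n_pool)
  picks <- integer(n_pool)
  random_rng <- derive_seed(config$seed, "random-scorer", prior$relevant_id)

  for (k in seq_len(n_pool)) {
    if ((k - 1L) %% config$retrain_every == 0L) {
      idx <- which(active)
      if (config$scorer == "nb") {
        w <- nb_weights(c1, c0, n1, n0, config$smoothing, config$balance_ratio)
        scores[idx] <- as.numeric(xp[idx, , drop = FALSE] %*% w$delta)
      } else {
        scores[idx] <- withr::with_seed(derive_seed(random_rng, k),
                                        runif(length(idx)))
      }
    }
    idx <- which(active)
    pick <- idx[which.max(scores[idx])]
    picks[k] <- pick
    active[pick] <- FALSE
    if (labels[[pool_ids[pick]]] == 1L) {
      c1 <- c1 + as.numeric(xp[pick, , drop = FALSE])
      n1 <- n1 + 1L
    } else {
      c0 <- c0 + as.numeric(xp[pick, , drop = FALSE])
      n0 <- n0 + 1L
    }
  }
  screening_trace(ordered_ids = pool_ids[picks],
                  labels_in_order = unname(labels[pool_ids[picks]]),
                  prior = prior, run_index = run_index, stage = stage)
}

#' Run a batch of simulations varying the relevant prior
#'
#' One screening run per chosen relevant prior record, mitigating the bias of
#' the starting paper: `n_runs = "all"` (default) runs once per relevant
#' record. All runs share the same seeded set of irrelevant prior records;
#' only the relevant prior varies.
#'
#' @param x A [corpus()].
#' @param stage Stage name or label column.
#' @param config A [simulation_config()].
#' @param n_runs Positive integer or `"all"`; values above the number of
#'   relevant records are clamped with a warning.
#' @return List of [screening_trace()] objects, `run_index` 1..n.
#' @export
run_batch <- function(x, stage, config = simulation_config(), n_runs = "all") {
  labels <- stage_labels(x, stage)
  rel_ids <- names(labels)[!is.na(labels) & labels == 1L]
  # feasibility is checked here too so the error predates any heavy work
  probe <- select_priors(x, stage, seed = config$seed,
                         n_irrelevant = config$n_prior_irrelevant)
  rel_order <- withr::with_seed(derive_seed(config$seed, "run-order"),
                                sample(rel_ids))
  if (identical(n_runs, "all")) {
    n_runs <- length(rel_order)
  } else {
    if (!is_scalar_number(n_runs) || n_runs < 1) {
      abort_config("`n_runs` must be a positive integer or \"all\"")
    }
    if (n_runs > length(rel_order)) {
      warn(sprintf("n_runs = %d exceeds the %d relevant records; clamped",
                   n_runs, length(rel_order)))
      n_runs <- length(rel_order)
    }
  }
  features <- fit_features(record_texts(x))
  lapply(seq_len(n_runs), function(i) {
    prior <- structure(list(relevant_id = rel_order[[i]],
                            irrelevant_ids = probe$irrelevant_ids,
                            seed = config$seed),
                       class = "prior_set")
    simulate_screening(x, stage, prior, config,
                       features = features, run_index = i)
  })
}
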
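#' Three-stage screening study on one corpus
#'
#' Runs the full simulation battery for each adjudication stage — clinician
#' triage, methodologist selection, final full-text inclusion — and
#' aggregates the metrics per stage. A stage with fewer than 2 relevant
#' records (or too few irrelevant records for the priors) cannot seed a
#' simulation and is marked `infeasible` rather than failed, with its
#' numeric fields `NA`.
#'
#' @param x A preprocessed [corpus()] with the stage label columns.
#' @param config A [simulation_config()]; its `stage` field is ignored
#'   (each stage is run in turn).
#' @param metric_cfg A [metric_config()].
#' @param n_runs Runs per stage, as in [run_batch()].
#' @param stages Character vector of stages to run.
#' @return A tibble with one row per stage: `stage`, `n_selected` (relevant
#'   count at the stage), `wss_mean`, `wss_sd`, `rrf_mean`, `rrf_sd`,
#'   `atd_fraction`, `atd_abstracts`, `n_runs`, `status`.
#' @export
run_three_stage_study <- function(x, config = simulation_config(),
                                  metric_cfg = metric_config(),
                                  n_runs = "all",
                                  stages = c("clinician", "methodologist",
                                             "fulltext")) {
  stopifnot(inherits(x, "corpus"))
  rows <- lapply(stages, function(stage) {
    labels <- stage_labels(x, stage)
    n_sel <- sum(labels == 1L, na.rm = TRUE)
    feasible <- tryCatch({
      select_priors(x, stage, seed = config$seed,
                    n_irrelevant = config$n_prior_irrelevant)
      TRUE
    }, screensim_infeasible_error = function(e) FALSE)
    if (!feasible) {
      return(tibble::tibble(stage = stage, n_selected = n_sel,
                            wss_mean = NA_real_, wss_sd = NA_real_,
                            rrf_mean = NA_real_, rrf_sd = NA_real_,
                            atd_fraction = NA_real_, atd_abstracts = NA_real_,
                            n_runs = 0L, status = "infeasible"))
    }
    traces <- run_batch(x, stage, config, n_runs = n_runs)
    s <- summarize_traces(traces, metric_cfg)
    tibble::tibble(stage = stage, n_selected = n_sel,
                   wss_mean = s$wss$mean, wss_sd = s$wss$sd,
                   rrf_mean = s$rrf$mean, rrf_sd = s$rrf$sd,
                   atd_fraction = s$atd$fraction,
                   atd_abstracts = s$atd$abstracts,
                   n_runs = s$n_runs, status = "ok")
  })
  out <- do.call(rbind, rows)
  if (!any(out$status == "ok")) {
    abort_infeasible("no stage of this corpus supports a simulation")
  }
  out
}

#' Aggregate per-dataset stage summaries into a study table
#'
#' Stacks per-dataset results from [run_three_stage_study()] and appends a
#' `Total` row per stage holding the unweighted mean of the per-dataset
#' means and their standard deviation across datasets. Infeasible rows are
#' excluded stage-wise; the exclusion counts are attached as attribute
#' `n_excluded`. The SD over a single dataset is `NA`, not 0.
#'
#' @param summaries Named list of [run_three_stage_study()] tibbles (names
#'   are dataset labels), or a single tibble already carrying a `dataset`
#'   column.
#' @return Tibble of per-dataset rows plus `Total` rows (`dataset ==
#'   "Total"`), with `n_selected` summed over contributing datasets.
#' @export
aggregate_datasets <- function(summaries) {
  if (is.data.frame(summaries)) {
    stopifnot("dataset" %in% names(summaries))
    tbl <- tibble::as_tibble(summaries)
  } else {
    nm <- names(summaries) %||% sprintf("dataset%02d", seq_along(summaries))
    tbl <- do.call(rbind, lapply(seq_along(summaries), function(i) {
      cbind(tibble::tibble(dataset = nm[[i]]), summaries[[i]])
    }))
  }
  stages <- unique(tbl$stage)
  excluded <- setNames(integer(length(stages)), stages)
  totals <- lapply(stages, function(st) {
    rows <- tbl[tbl$stage == st, , drop = FALSE]
    ok <- rows[rows$status == "ok", , drop = FALSE]
    excluded[[st]] <<- nrow(rows) - nrow(ok)
    tibble::tibble(dataset = "Total", stage = st,
                   n_selected = sum(rows$n_selected),
                   wss_mean = mean(ok$wss_mean), wss_sd = sd(ok$wss_mean),
                   rrf_mean = mean(ok$rrf_mean), rrf_sd = sd(ok$rrf_mean),
                   atd_fraction = mean(ok$atd_fraction),
                   atd_abstracts = mean(ok$atd_abstracts),
                   n_runs = sum(ok$n_runs),
                   status = sprintf("ok (%d dataset%s)", nrow(ok),
                                    if (nrow(ok) == 1L) "" else "s"))
  })
  out <- rbind(tbl, do.call(rbind, totals))
  attr(out, "n_excluded") <- excluded
  out
}

#' Label-noise degradation experiment
#'
#' Measures how screening-prioritization performance degrades as rater label
#' noise grows. For each false-inclusion rate in the grid and each
#' replicate, a synthetic corpus is generated (replicates share their text
#' and error draws across rates, so the comparison is paired and flips are
#' monotone in the rate), the clinician stage is simulated, and the mean
#' WSS at the configured recall level recorded. The monotone trend is
#' summarized as the Spearman rank correlation between the noise rate and
#' the mean WSS; under the noisy-label hypothesis it is negative.
#'
#' @param noise_grid Ascending vector of rater false-inclusion rates.
#' @param gen_config Base [generator_config()]; `rater_fp` is overridden by
#'   the grid.
#' @param n_replicates Corpora per grid point (at least 5 recommended for a
#'   stable trend).
#' @param seed Master seed.
#' @param sim_config A [simulation_config()] for the screening runs.
#' @param n_runs Runs per corpus (default 1; the replicates carry the
#'   averaging).
#' @param max_retries Regeneration attempts when a draw is infeasible.
#' @return List with `table` (tibble: `noise_rate`, `wss_mean`, `wss_sd`,
#'   `n_replicates`), `spearman_rho` (`NA` for a single-point grid) and
#'   `per_replicate` (tibble of all replicate-level means).
#' @export
noise_degradation_experiment <- function(noise_grid, gen_config = generator_config(),
                                         n_replicates = 20L, seed = 1L,
                                         sim_config = simulation_config(),
                                         n_runs = 1L, max_retries = 5L) {
  if (is.unsorted(noise_grid)) abort_config("`noise_grid` must be ascending")
  if (!is_scalar_number(n_replicates) || n_replicates < 1) {
    abort_config("`n_replicates` must be a positive integer")
  }
  if (n_replicates < 5) {
    warn("fewer than 5 replicates per grid point gives an unstable trend estimate")
  }
  cells <- list()
  for (rate in noise_grid) {
    for (j in seq_len(n_replicates)) {
      wss_val <- NA_real_
      for (attempt in 0:max_retries) {
        cfg <- gen_config
        cfg$rater_fp <- rate
        cfg$seed <- derive_seed(seed, "noise-replicate", j, attempt)
        wss_val <- tryCatch({
          cx <- generate_corpus(cfg)
          traces <- run_batch(cx, "clinician",
                              modify_config(sim_config,
                                            seed = derive_seed(seed, "sim", j, attempt)),
                              n_runs = n_runs)
          mean(vapply(traces, wss, 0))
        }, screensim_infeasible_error = function(e) NA_real_)
        if (!is.na(wss_val)) break
      }
      if (is.na(wss_val)) {
        abort_infeasible(sprintf(
          "could not generate a feasible corpus at noise rate %.2f after %d retries",
          rate, max_retries))
      }
      cells[[length(cells) + 1L]] <- tibble::tibble(
        noise_rate = rate, replicate = j, wss = wss_val)
    }
  }
  per_rep <- do.call(rbind, cells)
  tab <- do.call(rbind, lapply(unique(per_rep$noise_rate), function(rate) {
    v <- per_rep$wss[per_rep$noise_rate == rate]
    tibble::tibble(noise_rate = rate, wss_mean = mean(v), wss_sd = sd(v),
                   n_replicates = length(v))
  }))
  rho <- if (nrow(tab) < 2L) NA_real_ else
    cor(tab$noise_rate, tab$wss_mean, method = "spearman")
  list(table = tab, spearman_rho = rho, per_replicate = per_rep)
}

modify_config <- function(config, ...) {
  dots <- list(...)
  for (nm in names(dots)) config[[nm]] <- dots[[nm]]
  config
}
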
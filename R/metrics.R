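#' Metric configuration
#'
#' @param recall_level Recall level for work saved over sampling, in (0, 1];
#'   default 0.95 (WSS@95).
#' @param screen_fraction Screened fraction for relevant records found, in
#'   (0, 1]; default 0.10 (RRF@10).
#' @return A `metric_config` list.
#' @export
metric_config <- function(recall_level = 0.95, screen_fraction = 0.10) {
  check_fraction(recall_level, "recall_level", lo = 0, hi = 1, lo_open = TRUE)
  check_fraction(screen_fraction, "screen_fraction", lo = 0, hi = 1, lo_open = TRUE)
  structure(list(recall_level = recall_level, screen_fraction = screen_fraction),
            class = "metric_config")
}

#' Recall curve of a screening trace
#'
#' Cumulative count of relevant records against screening position: element
#' `k` is the number of relevant records among the first `k` screened.
#' Nondecreasing; its final value equals the pool's relevant count.
#'
#' @param trace A [screening_trace()].
#' @return Integer vector of length `n_pool`.
#' @export
recall_curve <- function(trace) {
  stopifnot(inherits(trace, "screening_trace"))
  cumsum(trace$labels_in_order)
}

#' Work saved over sampling (WSS)
#'
#' The proportion of the pool that need not be screened to reach the target
#' recall, minus the recall allowance. With `m = ceiling(r * R_pool)` relevant
#' records required and `n*` the first position at which the recall curve
#' reaches `m`,
#' \deqn{WSS@r = 100 \times ((N_{pool} - n^*)/N_{pool} - (1 - r)).}
#' At `r = 0.95` this is WSS@95: work saved at the cost of failing to
#' identify 5\% of relevant publications. Best case (all relevant first)
#' gives `100 * (0.95 - m/N)`, worst case -5.
#'
#' @param trace A [screening_trace()] with at least one relevant record.
#' @param config A [metric_config()].
#' @return Percentage.
#' @export
wss <- function(trace, config = metric_config()) {
  stopifnot(inherits(trace, "screening_trace"))
  if (trace$r_pool < 1L) abort_validation("trace has no relevant records")
  r <- config$recall_level
  m <- ceiling(r * trace$r_pool)
  curve <- recall_curve(trace)
  n_star <- match(TRUE, curve >= m)
  100 * ((trace$n_pool - n_star) / trace$n_pool - (1 - r))
}

#' Relevant records found (RRF)
#'
#' Percentage of relevant records retrieved after screening the first
#' `ceiling(p * N_pool)` records; `p = 0.10` gives RRF@10.
#'
#' @inheritParams wss
#' @return Percentage in \[0, 100\].
#' @export
rrf <- function(trace, config = metric_config()) {
  stopifnot(inherits(trace, "screening_trace"))
  if (trace$r_pool < 1L) abort_validation("trace has no relevant records")
  k <- ceiling(config$screen_fraction * trace$n_pool)
  100 * recall_curve(trace)[k] / trace$r_pool
}

#' Time to discovery of each relevant record
#'
#' For a relevant pool record first seen at screening position `k`, the time
#' to discovery is `k / N_pool` — the fraction of the pool screened before it
#' was found. Relevant records used as priors are not in the pool and so are
#' absent from the map. High TD flags hard-to-find records and candidate
#' noisy labels.
#'
#' @param trace A [screening_trace()].
#' @return Named numeric vector (record id -> TD fraction in (0, 1\]).
#' @export
time_to_discovery <- function(trace) {
  stopifnot(inherits(trace, "screening_trace"))
  pos <- which(trace$labels_in_order == 1L)
  setNames(pos / trace$n_pool, trace$ordered_ids[pos])
}

#' Average time to discovery (ATD)
#'
#' Mean of the time-to-discovery values pooled over all relevant records and
#' all runs. Reported both as a fraction of the pool and as an equivalent
#' abstract count (fraction times the mean pool size).
#'
#' @param traces A [screening_trace()] or list of them.
#' @return List with `fraction`, `abstracts` and `n_discoveries`.
#' @export
atd <- function(traces) {
  traces <- as_trace_list(traces)
  tds <- unlist(lapply(traces, time_to_discovery), use.names = FALSE)
  if (!length(tds)) abort_validation("no relevant records in any trace")
  frac <- mean(tds)
  list(fraction = frac,
       abstracts = frac * mean(vapply(traces, `[[`, 0, "n_pool")),
       n_discoveries = length(tds))
}

#' Rank records by how hard they were to find
#'
#' Records ranked by mean time to discovery across runs, descending; ties
#' broken by record id. The top of this ranking is where noisy labels hide.
#'
#' @param traces A [screening_trace()] or list of them.
#' @param top_k Number of records to return; larger than the number of
#'   discovered records returns the full ranking.
#' @return Tibble with `record_id`, `mean_td`, `n_runs` (runs in which the
#'   record was discovered).
#' @export
hard_to_find <- function(traces, top_k = 10L) {
  if (!is_scalar_number(top_k) || top_k < 1) {
    abort_config("`top_k` must be a positive integer")
  }
  traces <- as_trace_list(traces)
  tds <- lapply(traces, time_to_discovery)
  all_ids <- unique(unlist(lapply(tds, names), use.names = FALSE))
  if (!length(all_ids)) abort_validation("no relevant records in any trace")
  mean_td <- vapply(all_ids, function(id) {
    mean(unlist(lapply(tds, function(m) if (id %in% names(m)) m[[id]])))
  }, 0)
  n_runs <- vapply(all_ids, function(id) {
    sum(vapply(tds, function(m) id %in% names(m), FALSE))
  }, 0L)
  ord <- order(-mean_td, all_ids)
  out <- tibble::tibble(record_id = all_ids[ord],
                        mean_td = unname(mean_td[ord]),
                        n_runs = unname(n_runs[ord]))
  head(out, min(as.integer(top_k), nrow(out)))
}

#' Summarize a batch of runs
#'
#' Per-run WSS and RRF, their mean and standard deviation over runs, and the
#' pooled ATD — the aggregation used for each stage of the study tables.
#'
#' @param traces A [screening_trace()] or list of them.
#' @param config A [metric_config()].
#' @return List with `wss` (`mean`, `sd`, `per_run`), `rrf` (same shape),
#'   `atd` (see [atd()]) and `n_runs`.
#' @export
summarize_traces <- function(traces, config = metric_config()) {
  traces <- as_trace_list(traces)
  wss_runs <- vapply(traces, wss, 0, config = config)
  rrf_runs <- vapply(traces, rrf, 0, config = config)
  list(wss = list(mean = mean(wss_runs), sd = sd(wss_runs), per_run = wss_runs),
       rrf = list(mean = mean(rrf_runs), sd = sd(rrf_runs), per_run = rrf_runs),
       atd = atd(traces),
       n_runs = length(traces))
}

as_trace_list <- function(traces) {
  if (inherits(traces, "screening_trace")) traces <- list(traces)
  if (!length(traces) || !all(vapply(traces, inherits, TRUE, "screening_trace"))) {
    abort_config("expected a screening_trace or a non-empty list of them")
  }
  traces
}
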
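#' Synthetic corpus generator configuration
#'
#' Parameters of the synthetic title-abstract corpus generator. The defaults
#' emulate the structure of real guideline-screening datasets: a few hundred
#' records, low relevance prevalence, two imperfect correlated clinician
#' raters whose union over-includes (about half of clinician inclusions are
#' later relabeled irrelevant by a research methodologist), a further
#' full-text exclusion, and nested stage labels
#' (fulltext within methodologist within clinician).
#'
#' @param n_records Number of records N (>= 20).
#' @param prevalence True relevance prevalence, in (0, 0.5).
#' @param vocab_size Number of pseudo-word types.
#' @param signal_strength In \[0, 1\]: mixing weight of the class-specific
#'   topic in each class's token distribution. 0 makes relevant and
#'   irrelevant text indistinguishable; 1 gives disjoint vocabularies
#'   (perfectly separable classes).
#' @param doc_length Mean abstract length in tokens (Poisson, floored at 5).
#' @param title_length Title length in tokens.
#' @param rater_fp Per-rater false-inclusion probability (irrelevant labeled
#'   relevant).
#' @param rater_fn Per-rater false-exclusion probability (relevant labeled
#'   irrelevant).
#' @param rater_correlation Correlation of the two raters' errors, in
#'   \[0, 1\]: with this probability both raters share one error draw for a
#'   record, otherwise they err independently.
#' @param methodologist_exclusion Fraction of clinician inclusions relabeled
#'   irrelevant by the methodologist (default 0.49, the over-inclusion rate
#'   observed in guideline practice). False positives are removed first.
#' @param fulltext_exclusion Further fraction of methodologist inclusions
#'   excluded at full text (default 0.133).
#' @param nested If `TRUE` (default) the methodologist and full-text columns
#'   are carved out of the clinician inclusions, so the stages nest by
#'   construction; if `FALSE` they are drawn independently from truth with
#'   the same rater error rates.
#' @param seed Integer seed; generation is bitwise-deterministic given it.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_records = 300L, prevalence = 0.05,
                             vocab_size = 600L, signal_strength = 0.6,
                             doc_length = 60, title_length = 8L,
                             rater_fp = 0.03, rater_fn = 0.15,
                             rater_correlation = 0.1,
                             methodologist_exclusion = 0.49,
                             fulltext_exclusion = 0.133,
                             nested = TRUE, seed = 1L) {
  if (!is_scalar_number(n_records) || n_records < 20) {
    abort_config("`n_records` must be an integer >= 20")
  }
  check_fraction(prevalence, "prevalence", lo = 0, hi = 0.5,
                 lo_open = TRUE, hi_open = TRUE)
  if (!is_scalar_number(vocab_size) || vocab_size < 4) {
    abort_config("`vocab_size` must be an integer >= 4")
  }
  check_fraction(signal_strength, "signal_strength")
  if (!is_scalar_number(doc_length) || doc_length < 5) {
    abort_config("`doc_length` must be >= 5")
  }
  check_fraction(rater_fp, "rater_fp", hi_open = TRUE)
  check_fraction(rater_fn, "rater_fn", hi_open = TRUE)
  check_fraction(rater_correlation, "rater_correlation")
  check_fraction(methodologist_exclusion, "methodologist_exclusion", hi_open = TRUE)
  check_fraction(fulltext_exclusion, "fulltext_exclusion", hi_open = TRUE)
  structure(list(n_records = as.integer(n_records), prevalence = prevalence,
                 vocab_size = as.integer(vocab_size),
                 signal_strength = signal_strength,
                 doc_length = doc_length,
                 title_length = as.integer(title_length),
                 rater_fp = rater_fp, rater_fn = rater_fn,
                 rater_correlation = rater_correlation,
                 methodologist_exclusion = methodologist_exclusion,
                 fulltext_exclusion = fulltext_exclusion,
                 nested = isTRUE(nested), seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a synthetic labeled corpus
#'
#' Draws record relevance from Bernoulli(prevalence), renders each record as
#' a pseudo-title plus pseudo-abstract of tokens from a class-conditional
#' unigram mixture (divergence between the class distributions scales with
#' `signal_strength`), applies correlated rater noise, consolidates the
#' clinician stage as the union (OR) of the two raters, and carves the
#' methodologist and full-text stages out of the clinician inclusions with
#' false positives removed preferentially — so the adjudication stages are
#' nested by construction. Configurations yielding fewer than 2 truly
#' relevant records are redrawn a bounded number of times.
#'
#' @param config A [generator_config()].
#' @return A [corpus()] with label columns `truth`, `label_clinician1`,
#'   `label_clinician2`, `label_clinician`, `label_methodologist`,
#'   `label_fulltext`; the configuration is attached as attribute
#'   `generator_config`.
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(derive_seed(config$seed, "corpus"), {
    n <- config$n_records
    truth <- rbinom(n, 1L, config$prevalence)
    tries <- 0L
    while (sum(truth) < 2L && tries < 20L) {
      truth <- rbinom(n, 1L, config$prevalence)
      tries <- tries + 1L
    }
    if (sum(truth) < 2L) {
      abort_infeasible("could not draw >= 2 relevant records; raise `prevalence` or `n_records`")
    }

    vocab <- sprintf("w%04d", seq_len(config$vocab_size))
    half <- floor(config$vocab_size / 2)
    lam <- config$signal_strength
    base <- rep(1 / config$vocab_size, config$vocab_size)
    topic_rel <- c(rep(1 / half, half), rep(0, config$vocab_size - half))
    topic_irr <- c(rep(0, half), rep(1 / (config$vocab_size - half),
                                     config$vocab_size - half))
    p_rel <- (1 - lam) * base + lam * topic_rel
    p_irr <- (1 - lam) * base + lam * topic_irr

    draw_text <- function(is_rel, n_tokens) {
      paste(sample(vocab, n_tokens, replace = TRUE,
                   prob = if (is_rel) p_rel else p_irr),
            collapse = " ")
    }
    abs_len <- pmax(5L, rpois(n, config$doc_length))
    abstract <- vapply(seq_len(n),
                       function(i) draw_text(truth[i] == 1L, abs_len[i]), "")
    title <- vapply(seq_len(n),
                    function(i) draw_text(truth[i] == 1L, config$title_length), "")
    dup <- duplicated(normalize_title(title))
    if (any(dup)) {  # keep titles unique so preprocessing is a no-op
      title[dup] <- paste(title[dup], sprintf("vv%03d", which(dup)))
    }

    raters <- rater_noise_draw(truth, config)
    clin <- as.integer(raters$rater1 == 1L | raters$rater2 == 1L)
    if (config$nested) {
      meth <- stage_reduce(clin, truth, config$methodologist_exclusion)
      ft <- stage_reduce(meth, truth, config$fulltext_exclusion)
    } else {
      meth <- one_noisy_rater(truth, config$rater_fp, config$rater_fn)
      ft <- one_noisy_rater(truth, config$rater_fp, config$rater_fn)
    }

    rec <- tibble::tibble(
      record_id = sprintf("syn%05d", seq_len(n)),
      title = title, abstract = abstract,
      truth = truth,
      label_clinician1 = raters$rater1,
      label_clinician2 = raters$rater2,
      label_clinician = clin,
      label_methodologist = meth,
      label_fulltext = ft)
    out <- corpus(rec, source = sprintf("synthetic(seed=%d)", config$seed))
    attr(out, "generator_config") <- config
    out
  })
}

# Drop a fraction of a stage's inclusions, false positives first, then true
# positives if the quota exceeds the available false positives.
stage_reduce <- function(stage_labels, truth, exclusion_fraction) {
  incl <- which(stage_labels == 1L)
  n_remove <- round(exclusion_fraction * length(incl))
  if (n_remove == 0L) return(stage_labels)
  fps <- incl[truth[incl] == 0L]
  tps <- incl[truth[incl] == 1L]
  drop <- head(c(sample(fps), sample(tps)), n_remove)
  out <- stage_labels
  out[drop] <- 0L
  out
}

one_noisy_rater <- function(truth, fp, fn) {
  u <- runif(length(truth))
  flip <- u < ifelse(truth == 1L, fn, fp)
  as.integer(ifelse(flip, 1L - truth, truth))
}

# Shared-latent correlated flips; assumes an active RNG stream.
rater_noise_draw <- function(truth, config) {
  n <- length(truth)
  p_err <- ifelse(truth == 1L, config$rater_fn, config$rater_fp)
  shared <- runif(n) < config$rater_correlation
  u0 <- runif(n)
  u1 <- runif(n)
  u2 <- runif(n)
  f1 <- ifelse(shared, u0, u1) < p_err
  f2 <- ifelse(shared, u0, u2) < p_err
  list(rater1 = as.integer(ifelse(f1, 1L - truth, truth)),
       rater2 = as.integer(ifelse(f2, 1L - truth, truth)))
}

#' Apply correlated rater noise to a truth vector
#'
#' Each rater flips a relevant record to irrelevant with probability
#' `rater_fn` and an irrelevant record to relevant with probability
#' `rater_fp`. With probability `rater_correlation` a record's two raters
#' share a single error draw (both err or neither), otherwise they err
#' independently — a shared-latent construction giving error correlation
#' equal to `rater_correlation`. Deterministic given `config$seed`.
#'
#' @param truth Integer 0/1 vector.
#' @param config A [generator_config()].
#' @return List with integer vectors `rater1` and `rater2`.
#' @export
apply_rater_noise <- function(truth, config = generator_config()) {
  truth <- coerce_label(truth, "truth")
  if (anyNA(truth)) abort_validation("`truth` must not contain missing labels")
  withr::with_seed(derive_seed(config$seed, "raters"),
                   rater_noise_draw(truth, config))
}

#' Analytic Cohen's kappa of the rater-noise model
#'
#' Closed-form kappa implied by the generator's noise process: marginalizing
#' the shared-latent flips over the two truth classes gives the joint label
#' distribution of the two raters, hence the expected observed and chance
#' agreement and kappa. This is the oracle the generator's calibration is
#' searched against and its Monte-Carlo output is tested against.
#'
#' @param prevalence True relevance prevalence.
#' @param fp,fn Per-rater false-inclusion / false-exclusion probabilities.
#' @param rho Error correlation in \[0, 1\].
#' @return Kappa as a number; `NA` if chance agreement is 1.
#' @export
analytic_kappa <- function(prevalence, fp, fn, rho) {
  cells <- c(a = 0, b = 0, c = 0, d = 0)
  for (t in c(1L, 0L)) {
    w <- if (t == 1L) prevalence else 1 - prevalence
    f <- if (t == 1L) fn else fp
    both <- rho * f + (1 - rho) * f^2
    neither <- rho * (1 - f) + (1 - rho) * (1 - f)^2
    only_one <- (1 - rho) * f * (1 - f)
    if (t == 1L) {  # flip 1 -> 0
      cells <- cells + w * c(a = neither, b = only_one, c = only_one, d = both)
    } else {        # flip 0 -> 1
      cells <- cells + w * c(a = both, b = only_one, c = only_one, d = neither)
    }
  }
  p_o <- cells[["a"]] + cells[["d"]]
  p_a1 <- cells[["a"]] + cells[["b"]]
  p_b1 <- cells[["a"]] + cells[["c"]]
  p_e <- p_a1 * p_b1 + (1 - p_a1) * (1 - p_b1)
  if (p_e >= 1) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

#' Calibrate the noise model to a target kappa
#'
#' Searches the analytic kappa expression for rater parameters achieving a
#' requested agreement at the given prevalence and false-inclusion rate.
#' Kappa increases monotonically in the error correlation (reaching 1 as the
#' raters become copies), so the search picks the smallest false-exclusion
#' rate whose independent-raters kappa does not exceed the target and solves
#' for the correlation by root finding. Targets outside the attainable range
#' raise an infeasibility error stating the range.
#'
#' @param target_kappa Desired kappa, strictly below 1.
#' @param prevalence True relevance prevalence.
#' @param fp Per-rater false-inclusion probability (> 0).
#' @param fn_grid Candidate false-exclusion rates searched over.
#' @return List with `rater_correlation`, `rater_fn` and `achieved_kappa`
#'   (the analytic value, within 1e-6 of the target).
#' @export
calibrate_to_kappa <- function(target_kappa, prevalence, fp,
                               fn_grid = seq(0, 0.9, by = 0.01)) {
  check_fraction(prevalence, "prevalence", lo = 0, hi = 0.5,
                 lo_open = TRUE, hi_open = TRUE)
  check_fraction(fp, "fp", lo = 0, hi = 1, lo_open = TRUE, hi_open = TRUE)
  k0 <- vapply(fn_grid, function(fn) analytic_kappa(prevalence, fp, fn, 0), 0)
  lo <- min(k0)
  if (!is_scalar_number(target_kappa) || target_kappa >= 1 || target_kappa < lo) {
    abort_infeasible(sprintf(
      "target kappa %.3f unattainable at prevalence %.3f, fp %.3f: attainable range is [%.3f, 1)",
      target_kappa, prevalence, fp, lo))
  }
  i <- which(k0 <= target_kappa)[1L]
  fn <- fn_grid[[i]]
  if (k0[[i]] >= target_kappa - 1e-12) {
    rho <- 0
  } else {
    rho <- uniroot(function(r) analytic_kappa(prevalence, fp, fn, r) - target_kappa,
                   interval = c(0, 1), tol = 1e-9)$root
  }
  list(rater_correlation = rho, rater_fn = fn,
       achieved_kappa = analytic_kappa(prevalence, fp, fn, rho))
}
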
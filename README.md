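# screensim

Tools for studying **screening prioritization** in evidence synthesis — the
first, most labor-intensive pass of a systematic review or guideline update,
where humans judge hundreds to thousands of title–abstract records for
relevance. `screensim` simulates an active-learning screener on a labeled
corpus, measures how much work the prioritization saves, and — its main
point — quantifies how that saving collapses when the human labels feeding
the model are noisy.

The package is aimed at methodologists evaluating AI-assisted screening for
guideline development, where title–abstract labels pass through three
adjudication stages: triage by two clinicians, re-selection by a research
methodologist (who typically discards about half of the clinician
inclusions), and final full-text inclusion.

## What it computes

**The simulation.** Records are featurized once with TF-IDF
(`tf · (ln((1+D)/(1+df)) + 1)`, L2-normalized rows, lowercased unigrams of
≥ 2 word characters). Starting from prior knowledge of 1 relevant + 10
irrelevant records, a multinomial naive Bayes classifier (additive smoothing
α = 3.822, dynamically class-rebalanced) scores the unscreened pool, the
top-scoring record is "screened" (its true label revealed), the model is
retrained, and the loop repeats until the pool is exhausted. One run per
choice of relevant prior; all runs share the same seeded irrelevant priors.

**The metrics**, computed from the resulting screening order with
`N` = pool size, `R` = relevant records in the pool, `s(k)` = relevant found
among the first `k` screened:

- `WSS@95 = 100 · ((N − n*)/N − 0.05)` with `n*` the first position where
  `s(k) ≥ ⌈0.95 R⌉` — work saved over random sampling at 95 % recall;
- `RRF@10 = 100 · s(⌈0.10 N⌉)/R` — relevant records found after screening
  10 % of the pool;
- `TD(i) = k_i/N` and `ATD` = mean TD over records and runs — time to
  discovery; persistently high TD flags hard-to-find records and candidate
  noisy labels;
- recall curves, and Cohen's κ (`(p_o − p_e)/(1 − p_e)` from the 2×2
  contingency) for inter-rater agreement.

**The generator.** Synthetic corpora with topic-separable pseudo-text, low
prevalence, two correlated noisy raters (calibratable to a target κ via a
closed-form κ expression), and nested stage labels
(fulltext ⊆ methodologist ⊆ clinician) with false positives removed
preferentially at each stage — so every experiment here runs without any
data download.

## Worked example

```r
library(screensim)

cx <- generate_corpus(generator_config(n_records = 300, seed = 42))
cohens_kappa(cx$records$label_clinician1, cx$records$label_clinician2)
#> Cohen's kappa = 0.6538  (p_o = 0.9500, p_e = 0.8556, n = 300, dropped = 0)

study <- run_three_stage_study(cx, simulation_config(seed = 42), n_runs = 5)
study[, c("stage", "n_selected", "wss_mean", "rrf_mean", "atd_abstracts")]
#>           stage n_selected wss_mean rrf_mean atd_abstracts
#> 1     clinician         31    10.92    57.33        75.447
#> 2 methodologist         16    89.46   100.00         8.360
#> 3      fulltext         14    89.81   100.00         7.831
```

Reading the table: the two clinicians jointly flagged 31 records, of which
the methodologist kept 16 and full text confirmed 14. Simulating against the
noisy clinician labels, prioritized screening saves only ~11 % of the
reading effort at 95 % recall, because nearly half of the clinician
"relevant" targets are textually indistinguishable from irrelevant records.
Against the cleaner methodologist and full-text labels the same engine saves
~90 % of the effort and finds every relevant record within the first 10 % of
the pool (the average relevant record surfaces after ~8 abstracts). Noisy
labels make noisy machine learning; performance recovers as adjudication
removes the noise.

The degradation can be measured directly:

```r
noise_degradation_experiment(seq(0, 0.5, by = 0.1), n_replicates = 20,
                             seed = 1)$spearman_rho
#> [1] -1
```

A thin command-line front end over the same functions ships in
`inst/cli/screensim.R` (subcommands `generate`, `kappa`, `simulate`,
`metrics`, `study`, `noise`).

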
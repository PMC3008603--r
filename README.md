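# survsig

Survival-supervised two-metagene expression classifiers for recurrence-risk
stratification.

`survsig` is for researchers building prognostic gene-expression assays from
microarray (or any probe-by-sample) data with a right-censored outcome —
the canonical use case being recurrence risk in stage 2–3 colon cancer,
where a continuous risk score decides who is offered adjuvant therapy. The
package covers the full chain: chip quality control, intensity filtering and
reference-set median centering, survival-supervised probe selection,
rank-based model training, single-sample classification with a calibrated
confidence interval, Kaplan–Meier / log-rank / multivariate-Cox evaluation,
multi-site reproducibility analysis, and a synthetic-cohort generator so the
whole pipeline is testable without any data download.

## The method

1. **Screen.** Every probe *g* is tested in a multivariate Cox
   proportional-hazards model
   `h(t) = h0(t) exp(βg·xg + βa·age + βr·grade + βs·stage)`;
   probes with Wald *p* < 0.002 for βg pass.
2. **Stabilise.** The screen *and* the downstream model fit are repeated
   with each sample left out once (LOOCV). Probes selected in ≥ 20% of
   rounds form the signature; each round also yields an honest held-out
   risk score for the omitted sample.
3. **Compress.** Signature expression is converted to within-sample
   percentile ranks (0–100), mean-centred per probe, and projected onto the
   first two principal components — the two "metagenes". A Cox fit on the
   metagene scores s₁, s₂ gives the **prognostic index**
   `PI = β₁s₁ + β₂s₂`, signed so that higher PI = higher hazard.
4. **Classify.** The threshold is the 50th percentile of the held-out LOOCV
   indices; `PI ≥ threshold` is called high risk. Because the index depends
   only on the within-chip ordering of the signature probes, it is
   bit-invariant under any strictly increasing per-sample transform of the
   intensities — single chips classify one at a time, with a 95% interval
   `PI ± 1.96·σ` calibrated from multi-site replicate hybridisations.

## Worked example

```r
library(survsig)

cohort <- generate_cohort(sim_config(n_samples = 100, n_probes = 500,
                                     n_informative = 10, effect_size = 1.0,
                                     seed = 42))
filt <- filter_low_intensity(cohort$expression, threshold = 100,
                             reference = cohort$reference)
x <- median_center_chips(filt$matrix, cohort$reference)

trained <- train_signature(x, cohort$clinical, preprocess_state = filt$state)
trained$model
#> SignatureModel: 10 probes, 2 metagene(s)
#>   metagene Cox coefficients: 0.0140, 0.0187
#>   classification threshold: 0.3268 (50th percentile of training indices)

preds <- classify(trained$model, x)
head(preds, 3)
#>             sample_id prognostic_index ci_low ci_high risk_group borderline
#> SAMPLE_001 SAMPLE_001       -1.6127814     NA      NA        low         NA
#> SAMPLE_002 SAMPLE_002        0.9276437     NA      NA       high         NA
#> SAMPLE_003 SAMPLE_003        0.1616542     NA      NA        low         NA
# (ci_low/ci_high fill in once a replicate s.d. has been calibrated,
#  e.g. model <- set_replicate_sd(model, rep_stability$mean_sd))

cl <- as.data.frame(cohort$clinical)
logrank_test(cl$time_months, cl$event, preds$risk_group, horizon_months = 60)
#> log-rank chi-square = 28.2328, p = 1.076e-07
#> HR (low vs high) = 0.18, 95% CI 0.09-0.37
```

The trained model found the 10 planted informative probes, split the
cohort 50/50 at the LOOCV median, and the high-risk group carries a ~5.5×
hazard of recurrence (1/0.18) — the generator planted a log-hazard of 1.0
per s.d. of the latent risk factor. `risk_group_table()` produces the
per-stage survival table and `multivariate_report()` the adjusted
hazard-ratio table; `save_model()` / `load_model()` round-trip the model as
versioned JSON with bit-stable predictions.

A command-line wrapper lives at `inst/scripts/survsig` with subcommands
`simulate`, `qc`, `train`, `predict`, `evaluate`, `replicates`; every run
writes a JSON manifest with the resolved parameters and output digests.

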
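---
title: "Methods: the two-metagene survival classifier"
author: "survsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the two-metagene survival classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survsig)
```

## The problem

Patients with stage 2-3 colon cancer face a genuinely uncertain prognosis:
a substantial minority recur after surgery and might benefit from adjuvant
chemotherapy, while the majority would be over-treated by it. `survsig`
implements a survival-supervised gene-expression classifier for exactly this
kind of setting: given a probe-by-sample expression matrix (MAS5-style
normalised microarray intensities) and a clinical table with a right-censored
recurrence endpoint, it selects probes whose expression predicts outcome
*independently of* the standard clinical covariates, compresses them into two
"metagene" scores, and turns those into a single continuous **prognostic
index** with a high/low risk call per patient.

## The model

### Probe screening

For every probe $g$, a multivariate Cox proportional-hazards model is fitted:

$$
h_i(t) = h_0(t)\,
\exp\!\big(\beta_g x_{gi} + \beta_a\,\text{age}_i + \beta_r\,\text{grade}_i +
\beta_s\,\text{stage}_i\big)
$$

with grade and stage entering as ordinal numerics (mirroring the single
coefficient per covariate reported in standard multivariate tables). The
probe passes the screen when the two-sided Wald test of $\beta_g$ gives
$p < \alpha$, with $\alpha = 0.002$ by default. The Cox machinery (Efron or
Breslow ties, Newton-Raphson with step-halving, tolerance $10^{-9}$ on the
coefficient change, at most 100 iterations) is implemented in compiled code
because one screen is tens of thousands of fits and the cross-validation
below repeats the screen once per sample. Monotone separation is detected by
a coefficient-magnitude guard ($|\beta| > 20$) and reported as
non-convergence; the screen records such probes as unselected rather than
aborting, so a single degenerate probe cannot crash a training run.

### Stability selection by LOOCV

Probe selection at a hard threshold is noisy, so the whole training
procedure is wrapped in leave-one-out cross-validation: for each sample, the
screen *and* the metagene fit are redone on the remaining $n-1$ samples, and
the held-out sample's prognostic index is computed from that round's model.
Carrying the selection inside the loop is what makes the held-out indices
honest; selecting once on the full data and "validating" by LOOCV would leak
information. Probes selected in at least 20% of the rounds form the
signature. Rounds in which no probe passes the screen are recorded as empty
and contribute to the denominator unchanged.

### Percentile ranks and the metagene model

Expression over the signature probes is converted, within each sample, to
percentile ranks on $[0, 100]$: the value with (average-tie) rank $r$ among
$m$ maps to $100 (r-1)/(m-1)$. Two consequences drive this choice:

* the index of a future chip depends only on the *ordering* of its own
  signature probes, so any strictly increasing distortion of a chip's
  intensities (lab effects, scanner gain, scale convention) leaves the call
  untouched — the property the acceptance tests assert bit-exactly;
* no cohort statistics are needed at prediction time, so single chips can be
  classified one at a time.

An all-constant input maps to 50 everywhere by convention. Ranks are
mean-centred per probe (the centring vector is stored in the model) and the
first two principal components computed *without* variance scaling — ranks
already share the 0-100 scale, and rescaling would undo the point of
ranking. The two PC score vectors are the metagenes. A two-covariate Cox fit
on them gives coefficients $\beta_1, \beta_2$, and the prognostic index of a
sample with centred rank vector $\tilde r$ is the linear predictor

$$
\mathrm{PI} = \beta_1 \langle w_1, \tilde r\rangle +
\beta_2 \langle w_2, \tilde r\rangle .
$$

We read "weighted average of the two principal component values" as this
linear predictor without dividing by $\beta_1 + \beta_2$: any positive
rescaling of the index is strictly monotone and therefore cannot change any
median-threshold classification, and the linear predictor is the canonical
supervised-principal-components risk score. Component signs are flipped so
that every retained $\beta_j \ge 0$; a higher index then always means a
higher estimated hazard. When the second component carries essentially no
variance (relative eigenvalue below $10^{-8}$, which happens when the stable
probes are few and strongly redundant) the model falls back to a single
metagene with a warning rather than fitting noise.

### Threshold and classification

The classification threshold is the 50th percentile of the held-out LOOCV
indices, so by construction half the training series (to within the
$\lceil n/2 \rceil$ integer split) is called low risk. A prediction exactly
at the threshold is called **high** risk — the conservative direction for a
boundary case in a treatment-selection assay; a median threshold leaves the
tie direction open, so the convention has to be fixed somewhere. Every valid
input receives a call; there is no unclassifiable zone. When a calibrated
replicate standard deviation is available, each call carries a 95% interval
$\mathrm{PI} \pm 1.96\,\hat\sigma$ and is annotated as *borderline* when the
interval straddles the threshold.

## Preprocessing and chip QC

Training preprocessing is: (1) drop probes whose median linear intensity
across training samples is below 100 (the conventional background floor;
the boundary value 100 itself is retained since the rule is "< 100"), and
record the retained universe for prediction-time reuse; (2) log2-transform
(linear input floored at 1 first); (3) median-centre each chip on a
reference probe set of nominally 100 low-variance probes, making each
sample's reference median exactly zero. Centring proceeds when at least 50%
of the reference probes are present (warning) and errors below that floor.

The chip-QC module computes four metrics per chip; the published assay's
quality system is proprietary, so the definitions here are this package's
own, each mapping onto a factor such systems advertise:

| metric | definition | default window |
|---|---|---|
| `background_estimate` | mean log2 intensity of the dimmest 2% of probes | (0, 10) |
| `scale_factor` | chip 2%-trimmed mean / cohort median trimmed mean (linear) | (0.25, 4) |
| `signal_to_noise` | (97.5th − 2.5th percentile log2) / s.d. of the background region | ≥ 2 |
| `replicate_probe_cv` | median CV across genes with ≥ 2 probes (needs a mapping) | ≤ 0.5 |

The defaults are deliberately wide — they catch saturated chips,
order-of-magnitude scaling errors and gross noise, not biology. Deployments
should tighten the windows to the empirical distribution of their own clean
chips, which is exactly what the test suite does when it checks that a chip
with 10× inflated noise is flagged. QC log-intensities are computed without
flooring so that the background tail keeps its spread on degenerate chips.

## Evaluation

Kaplan-Meier curves use the product-limit estimator; "5-year" summaries
censor follow-up beyond a 60-month horizon at the horizon. The two-group
log-rank test uses the standard hypergeometric variance with tie
correction; with no ties it coincides with the score test of the
binary-covariate Cox fit (asserted to $10^{-6}$ in the tests). Because
survival comparisons are conventionally reported as "log-rank $p$, HR
(95% CI)", the log-rank result carries the hazard ratio from an
*unadjusted* one-covariate Cox fit on the group label; adjusted hazard
ratios appear only in the multivariate report, which fits one Cox model on
age, gender, grade, stage, optional therapy flags and the risk-group call,
and rejects exactly collinear covariate pairs by name.

## Reproducibility calibration

A deployed single-sample assay needs an error bar. Following the
multi-laboratory replicate design (pooled RNA samples hybridised repeatedly
at several sites), `replicate_stability()` computes, per sample, the mean
index per site and the standard deviation across site means; the average of
those standard deviations calibrates the 95% interval
($\pm 1.96\,\hat\sigma$) and is also reported as a fraction of the
prognostic-index range observed in the training LOOCV indices. Within-site
replicate runs are compared by one-way ANOVA on replicate number after
removing per-sample means (Kruskal-Wallis configurable); the published
analysis states only "no significant difference ($P > 0.05$)" without naming
a test, so the choice is ours and is deliberately generic. The interval is
symmetric on the index scale.

## The synthetic-data generator

`generate_cohort()` emulates the structure the pipeline assumes, not
microarray physics:

* per-probe mean log2 intensities are Gaussian (log-normal intensities),
  location 8, scale 1.5, with per-cell noise s.d. 0.4;
* a latent standard-normal risk factor $z_i$ per sample enters the
  informative probes **with alternating sign** (half up-, half
  down-regulated). This is not cosmetic: prognostic signatures genuinely
  contain both directions, and a purely one-sided informative set would
  shift all signature probes together and cancel out of within-sample
  ranks, leaving a rank-based index blind to it;
* survival times are exponential proportional hazards,
  $\lambda_i = \lambda_0 \exp(\text{effect} \cdot z_i + 0.01(\text{age}_i-65)
  + 0.2(\text{grade}_i-2) + 0.4(\text{stage}_i-2))$ with
  $\lambda_0 = 0.01$/month, so median event times sit at a few years as in
  recurrence cohorts;
* censoring is independent exponential with its rate solved numerically so
  the expected censored fraction equals the target (default 30%);
* 10% of probes are planted below the intensity filter in every sample
  (capped just under 100), and 100 near-constant reference probes are
  included, sitting well above the filter;
* defaults (n = 200 samples, 2000 probes, 20 informative at log-hazard 0.8
  per s.d., stage mix weighted to 2-3) represent a single training cohort
  at a size where the full LOOCV training runs in about a minute. The acceptance
  checks use these sizes; unit tests use smaller cohorts (tens of samples,
  hundreds of probes) built by the same generator.

What the generator does **not** emulate: probe-level PM/MM noise structure,
correlated gene networks beyond the single latent factor, batch effects
confounded with outcome, or non-proportional hazards. Passing tests
therefore demonstrate that the algorithmic chain is correct and calibrated
under its own assumptions — not that any particular signature will validate
on real tumours.

## Numerical choices and edge cases

* Cox convergence: tolerance $10^{-9}$ on the max coefficient change,
  step-halving on any likelihood decrease, Efron ties by default (exact
  when untied, conventional otherwise).
* Wald inference throughout ($z = \beta/\mathrm{se}$); the likelihood-ratio
  test is available and agrees within 10% on well-conditioned fits.
* The hypergeometric overlap tail is summed exactly in log space
  (`lchoose` + log-sum-exp), so $p$-values near $10^{-7}$ lose no
  precision.
* Percentile-rank ties take average ranks; the $(m-1)$ denominator pins the
  endpoints at exactly 0 and 100.
* Model serialisation is versioned JSON at full precision (`digits = NA`);
  load-then-predict reproduces indices to better than $10^{-12}$.
* The log-rank permutation check in the acceptance suite uses a toy with a
  mid-range statistic: at $n = 8$ the permutation null is supported on
  $\binom{8}{4} = 70$ label splits, so agreement with the 1-df chi-square
  approximation is limited by that granularity in the tails, not by
  Monte-Carlo error.

## Known limitations

* The screen fits one probe at a time; strongly correlated probes are
  selected or dropped together, and the stability frequencies reflect that
  redundancy rather than resolving it.
* Grade and stage as ordinal numerics assume roughly linear log-hazard
  steps between adjacent categories.
* LOOCV is $O(n)$ full retrainings; cohorts far beyond a few hundred
  samples would want a blocked cross-validation instead.
* The 95% prediction interval assumes the between-site variation observed
  on pooled replicates transfers to clinical chips, and is symmetric on the
  index scale.
* No gene-level collapsing of probes, no penalised alternatives to the
  hard screen, and at most two metagenes.
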
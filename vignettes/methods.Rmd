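---
title: "Methods: regulon inference, activity balance and prognosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regulon inference, activity balance and prognosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(maabalance)
```

This vignette is the package's own account of its models and numerical
choices: what each stage assumes, which parameters matter, what the
synthetic generator does and does not emulate, and where the design was
genuinely open. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## 1. The model in one paragraph

Two master-regulator transcription factors compete for control of a
differentiation program; in most tumors one is strongly active while the
other is switched off. Per-sample activity of each regulator is estimated
as a normalized enrichment score (NES) of its regulon — the set of its
putative targets, each with a regulation direction (mode) and a confidence
weight — on a rank-transformed expression signature. The Mean Absolute
Activity, $MAA = (|a_1| + |a_2|)/2$, measures how decisively *either*
program prevails: high MAA is an intact switch, MAA near zero a broken
one. MAA is then treated as a prognostic biomarker: dichotomized at a
maximally selected cut-point, binned into five strata, and entered into
Cox proportional-hazards models.

## 2. Mutual-information regulon screen

### Estimator

`estimate_mi()` rank-transforms both vectors (mid-ranks on ties),
discretizes each into $B = \max(2, \lfloor\sqrt{n/5}\rfloor)$
equal-frequency bins, and computes the plug-in mutual information of the
joint histogram in nats. Rank transformation makes the estimate *exactly*
invariant to strictly monotone transforms of either variable — the
property that lets the whole pipeline ignore whether expression is on a
linear, log, or scaled-estimate scale.

Two variants are exposed and the distinction is deliberate:

* `correction = "mm"` (default) subtracts the Miller–Madow occupancy term
  $(\hat m_{xy} - \hat m_x - \hat m_y + 1)/(2n)$ and clamps to
  $[0, \ln B]$. The raw plug-in estimator carries an upward bias of order
  $B^2/2n$, which at $n = 10^4$, $B = 44$ is ≈ 0.09 nats — large enough
  to spoil agreement with the Gaussian closed form
  $-\tfrac12\ln(1-\rho^2)$ at the ±0.05 tolerance our own acceptance
  check uses. The corrected estimate passes it with margin. The upper
  clamp is principled (MI of two $B$-level variables cannot exceed
  $\ln B$) and keeps the diagonal identity case at exactly $\ln B$.
* `correction = "none"` is the *screening statistic*. The corrected
  estimate has an atom at zero (roughly half of independent-pair
  estimates clamp to 0), which would put a large point mass at $p = 1$
  and destroy null p-value uniformity. The uncorrected plug-in value is
  continuous under permutation, so empirical p-values are exactly
  calibrated. `build_null()` and `infer_isoform_targets()` therefore use
  `"none"` on both sides of the comparison; bias is irrelevant there
  because null and observed statistics share it.

### Significance and the extreme threshold

The permutation null (`build_null()`, default `n_perm = 1000`) pools MI
values of the regulator vector against permuted expression rows. Because
the statistic is rank-based, the tie-free null law depends only on $n$
and the bin rule — one pooled null calibrates every candidate gene of a
cohort, which is why a single model serves a 20k-gene screen.

Within the observed null range, $p = (k+1)/(n_{perm}+1)$. The default
inclusion bound, $\alpha = 10^{-130}$, is unreachable by raw permutation,
so beyond the null maximum an exponential tail takes over:
$p(m) = \frac{1}{n_{perm}+1} \exp\{-(m - \max)/\hat\theta\}$ with
$\hat\theta$ the mean exceedance over the null's 95th percentile. This is
strictly decreasing and below $1/n_{perm}$ by construction. How the
original large-cohort analysis computed p-values that extreme is not
public; the fitted tail is this package's stand-in, and a `top_k`
alternative (keep the $k$ highest-MI genes) is offered because the
screen's purpose is reliable regulons of controlled size. On desk-scale
synthetic cohorts no gene reaches $10^{-130}$; the examples and tests run
the screen at $\alpha = 10^{-6}$.

Mode and weight are assigned from the Spearman correlation between
regulator and target (sign and absolute value respectively) — the
original study does not state whether its regulons carried weights, so we
adopt the convention the activity model needs. Per-isoform regulons are
merged by set union, keeping for each gene the entry with the largest
weight (ties: larger MI, then smaller gene id). Pruning by the
data-processing inequality is omitted: nothing indicates indirect edges
were removed *after* the extreme significance screen, and at these
thresholds the screen itself is the stronger filter (`dpi_epsilon` is a
reserved config hook).

## 3. Activity as rank enrichment

`rank_signature()` maps each gene's cross-sample ranks through
$\Phi^{-1}(r/(n+1))$; the signature is thus *relative to the cohort
itself* (the choice of reference signature in the original study is not
stated; cohort-relative is the common default for sample-wise activity
inference). `compute_nes()` is the weighted signed average
$\sum w_g m_g q_g / \sqrt{\sum w_g^2}$ — a single-tail, simplified aREA
statistic. Under a regulon independent of the signature, the NES is
asymptotically standard normal (its null mean/sd and normality are
acceptance-checked), so activities from different regulons share a scale.
A floor of 10 overlapping targets is enforced loudly; rescaling a
5-target score to look comparable would be worse than failing.

The simplifications relative to full VIPER (no three-tail combination, no
pleiotropy correction, no bootstrap) are intentional: the downstream
index uses only the signed magnitude of the two activities.

## 4. MAA, strata, cut-point

`compute_maa()` is the exact semi-sum of absolute activities. The
five-stratum binning is left-closed/right-open on
$\{0,1,2,3,4,\infty\}$; the published interval table leaves the point 4
formally unassigned, and we extend the left-closed convention so the bins
partition $[0,\infty)$. Dichotomization assigns ties at the threshold to
"above" (the published description says only "above and below"); the tie
rule is recorded in the output attributes.

The nested log expression ratio $\log_2(\log_2 e_1 / \log_2 e_2)$ is
undefined when either expression is ≤ 1; such samples are flagged and
counted, never dropped silently, and no acceptance test pins ratio values
numerically because the original normalization (scaling, offset) is
unstated.

The optimal cut-point is read as a *maximally selected* statistic: an
exhaustive scan of every unique MAA value between the 10th and 90th
percentiles, maximizing the two-group log-rank statistic. The published
wording ("optimal cut point of the Cox regression model") is ambiguous; a
second mode (`cox_scan`, maximizing the Wald chi-square of the
dichotomized indicator) is provided and the two agree on monotone-effect
data (tested). The headline p-value is the uncorrected log-rank p at the
selected threshold, matching the original report; because selection
inflates it, a permutation-adjusted p (re-running the full scan on
biomarker permutations) is available behind `permutation_p`.

## 5. Survival machinery

Kaplan–Meier, log-rank and Cox fits are wrapped from the `survival`
package behind strict contracts: Efron ties by default (Breslow available
— and used by the duplication-invariance test), convergence tolerance
$10^{-9}$ with ≤ 50 iterations, hard errors (not warnings) on monotone
likelihood or non-convergence, per-model complete-case handling with
logged drop counts. Wald 95% CIs and p-values reproduce the
`HR (95% CI)` schema of clinical tables. The multivariate model uses MAA,
sex, pooled stage (IIIA/IIIB → III, reference I), age and pack-years;
per-stage univariate fits keep the fine-grained stage labels and skip
strata with fewer than 10 events.

## 6. The synthetic world

`generate_cohort()` states the world the analysis assumes; its defaults
are fixed and are not tuned to test outcomes:

* **Latent polarity** $d = s\,b$, $s = \pm1$ equiprobable; $b \sim
  \mathrm{Beta}(5, 1.5)$ for a polarized fraction $\pi = 0.8$ of samples,
  $b \sim \mathrm{Beta}(1.5, 5)$ otherwise — the "crowded corners, sparse
  center" geometry of the observed activity scatter.
* **Activities** $A_1 = c\,d + \varepsilon$, $A_2 = -c\,d + \varepsilon$,
  jitter sd 0.1, scale $c = 4$ so that true MAA spans the published
  stratum range (0–6) and the published threshold 2.92 is interior.
* **Regulons** of 111 and 135 signed targets (the published sizes), modes
  70% activating, weights Uniform(0.5, 1), target noise sd 0.25 on the
  log2 scale; background genes are pure noise. Regulator expression
  follows its activity and is split 60/40 over two designated isoforms.
* **Survival**: exponential event times with hazard
  $h_0 \cdot \mathrm{HR}^{MAA}$, $\mathrm{HR} = 0.74$ per MAA unit (the
  published multivariate estimate) and $h_0 = 4\times10^{-4}$/day
  (median ≈ 4.7 years at MAA 0, a realistic NSCLC scale); censoring is
  Uniform$(0, c_{max})$ with $c_{max}$ solved by `uniroot` so the
  expected censored fraction matches the request (default 30%).
* **Binary features** are Bernoulli with group rates switching at MAA
  2.92; defaults mirror the published mutation frequencies (75.9%/59.6%
  for the TP53-like feature, etc.).
* **Reproducibility**: one master seed; named substream seeds (latent,
  expression, survival, censoring, features, clinical) derived from it,
  so perturbing one block never shifts another. Ground truth is written
  to a separate `truth.json` and never into analysis-facing files.

What the generator does **not** emulate: isoform diversity beyond two
designated isoforms per regulator, count noise (expression is log-normal,
not negative-binomial), methylation/copy-number structure, batch effects,
or stage–MAA confounding (stage hazards default to 1 and are independent
of MAA). A green end-to-end test therefore establishes that the pipeline
recovers the planted statistical structure — not that it would reproduce
any particular real-cohort number.

One consequence of the stated world deserves emphasis: because both
regulators are driven by a *single* latent polarity, every target of
either regulator is statistically dependent on both regulators'
expression. An MI screen seeded from TF1 therefore legitimately recovers
TF2's targets too — they are not estimator false positives (the real
regulons also share targets). End-to-end recovery is consequently scored
as: recall of the regulator's own planted targets, plus contamination by
*background* genes (targets of neither). Per-regulator selectivity is
tested separately on a planted design with TF-specific targets and
independent background, where false discoveries are well defined.

## 7. Association screens

Welch t (Satterthwaite df) for numeric features, two-sided Fisher exact
(probability-mass rule) for binary features; BH correction everywhere
except the mutation screen, which uses Bonferroni; adjusted p < 0.05
declares significance. The odds ratio reported is the sample
cross-product ratio, with a Haldane–Anscombe 0.5 correction applied for
display only when a zero cell exists — the p-value never uses it. The
negative-binomial differential-expression stage of the original workflow
is a published external tool and is deliberately replaced by the Welch
screen on log-scale values (a documented deviation, flagged in the
output's method tag). Drug–MAA association reports the Pearson
correlation of ln(IC50) with MAA and the geometric mean IC50 fold change
of low- versus high-MAA lines, sorted by absolute log fold change; drugs
with under 8 usable lines or constant IC50 are skipped with warnings.

## 8. Numerical and interface decisions

* Aggregation: `sum` for regulator expression across designated isoforms;
  `max_variance` for collapsing transcript-level matrices, with variance
  ties broken toward the lexicographically smallest id (deterministic
  builds).
* `log_transform` pseudocount defaults to 1.0 (the source analyses do not
  state an offset; 1 keeps zeros at zero and is the field's default).
* Stage labels are normalized case-insensitively with "Stage" prefixes
  and whitespace stripped; unknown labels become missing with a warning.
* The rank signature requires ≥ 20 samples and `estimate_mi` ≥ 20
  observations: below that, equal-frequency binning and rank quantiles
  are too coarse to mean anything, and the functions fail loudly.
* Config files are YAML or JSON (by extension), validated by one schema;
  `run_all()` stamps each run with a config hash, the seed and package
  version in `manifest.json`, so artifact directories are auditable.
* All pipeline randomness (permutation streams, simulation substreams)
  derives from the single config seed; reruns are byte-identical
  (tested).

## 9. Known limitations

* The exponential-tail extrapolation reaching $10^{-130}$ is a modeling
  convenience: the true null tail beyond the permutation range is
  unknown, and those p-values should be read as "far beyond permutation
  resolution", not as literal probabilities.
* NES magnitude grows with regulon coherence, so the *per-unit* Cox HR on
  estimated MAA is not commensurate with a per-unit HR on the latent
  activity scale; only scale-free comparisons (correlations, ranks,
  log-rank p) transfer between the two.
* The cut-point's headline p-value is selection-biased by design (to
  match the original report); use `permutation_p` when an honest test of
  association is needed.
* Proportional-hazards diagnostics are out of scope; the Cox wrapper
  fails on separation and non-convergence but does not test
  proportionality.
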
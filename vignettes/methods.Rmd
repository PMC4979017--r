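---
title: "Methods: from raw Ct profiles to a validated voting classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw Ct profiles to a validated voting classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirvote)
```

mirvote builds diagnostic classifiers from qPCR cycle-threshold (Ct)
profiles of circulating miRNAs. This vignette documents the statistical
model of each stage, the package's default parameters and why they were
chosen, and the design decisions and limitations a user should know before
trusting a result.

## The data model

A `ct_matrix` is a samples × probes matrix of Ct values. A probe is
**detected** in a sample when its Ct is finite and strictly below the
detection limit (default 32 cycles); "Undetermined" instrument tokens and
missing wells are stored as `NA` and treated as undetected. Where a numeric
stand-in for an undetected reaction is required (percentile computation,
normalizer values), the imputation ceiling of 40 cycles — the customary
maximum cycle number of the instrument — is used, never silently elsewhere.

Metadata carries `sample_id`, `group` (`CASE`, `CONTROL`, or
`OTHER:<label>` for extra panels such as benign disease), `cohort`
(`TRAINING`/`VALIDATION`), optional `stage` (I–IV) and `histology`, and an
`is_calibrator` flag valid only on training samples.

## Stage 1 — quality control

Three filters run in a fixed order:

1. **Spike-in filter.** Samples in which the exogenous spike-in probe
   (default `ath-miR-159a`) is undetected are removed; an undetected
   spike-in indicates failed RNA extraction or RT, not biology.
2. **Detectability screen.** Probes detected in no retained sample are
   dropped from all downstream stages.
3. **Percentile filter.** A sample whose 25th-percentile Ct (undetected
   imputed at the ceiling, quantile type 7) is at or above the detection
   limit is removed: if three quarters of its reactions sit at or past the
   limit, the profile is dominated by censoring.

The order matters and is part of the contract: the percentile filter sees
only spike-passing samples and endogenous probes.

## Stage 2 — normalizer selection

Candidate normalizers are probes detected in **every** QC-retained sample.
Each candidate's stability is the two-group model-based estimate of
Andersen et al. (2004) (the "NormFinder" decomposition): expression is
modelled as gene + sample + group×gene interaction; the interaction
estimates are double-centered, variance-shrunken toward zero, and combined
with the intra-group sampling SD into a stability value
$\rho_i = \text{mean}_g\left(|\tilde d_{ig}| + \sqrt{\widehat{\text{Var}}(d_{ig})}\right)$,
where smaller is more stable. The implementation was verified against an
independent loop-based transcription of the published algebra (agreement to
numerical precision) and against constructed designs with known answers.

Because stability is an estimate, selection is wrapped in a stratified
bootstrap: samples are resampled within group (group sizes preserved),
stability recomputed per replicate, and candidates ranked by the **median**
of their bootstrap stabilities (10,000 replicates by default; each
replicate draws from a deterministic substream of the seed, so runs are
exactly reproducible and individual replicates can be reconstructed). The
top 3 candidates form the normalizer set; ties are broken by probe id and
reported.

## Stage 3 — normalization

For each sample, the normalizer value is the mean Ct of the normalizer
probes (undetected imputed at the ceiling with a warning). Then

- $\Delta Ct(s, g) = Ct(s, g) - \text{normalizer value}(s)$,
- $\Delta\Delta Ct(s, g) = \Delta Ct(s, g) - \overline{\Delta Ct}_{\text{calibrators}}(g)$,
- $z(s, g) = (\Delta\Delta Ct(s, g) - \mu_g) / \sigma_g$,

where the calibrator mean is taken over 22 designated training samples
(honoring `is_calibrator` flags when present, otherwise a seeded random
draw) and $\mu_g, \sigma_g$ are the mean and SD of $\Delta\Delta Ct$ over
**all** training samples. All of these are frozen into a
`normalization_params` object whose fingerprint travels with the model;
validation samples are transformed with training parameters and are never
refit. Probes with zero training variance are flagged and excluded rather
than producing infinite z-scores. Values remain on the (log-scale) Ct
scale throughout; no conversion to fold change ($2^{-\Delta\Delta Ct}$) is
applied, since the classifier is affine-invariant per feature.

## Stage 4 — weighted-voting classification

Features are probes detected in at least 10% of training **cases**,
excluding the normalizer set. Each feature $g$ gets a signal-to-noise
weight

$$w_g = \frac{\mu_{\text{case}}(g) - \mu_{\text{control}}(g)}
             {\sigma_{\text{case}}(g) + \sigma_{\text{control}}(g)},$$

with $n-1$ sample SDs and the denominator floored at $10^{-6}$ to keep
degenerate folds finite. The decision boundary per feature is the midpoint
$b_g = (\mu_{\text{case}} + \mu_{\text{control}})/2$; a sample's vote on
$g$ is $w_g (x_g - b_g)$ and the call is POSITIVE iff the vote sum is
strictly positive.

The number of features $k$ is chosen by repeated stratified 10-fold
cross-validation (10,000 random partitions by default). Feature ranking by
$|w|$ happens **inside** every fold on its training nine-tenths, so the
held-out error is honest; $k$ ranges over 2–50 and the chosen $k$
minimizes the mean per-fold-model misclassification count, taking the
smallest $k$ on ties. The final feature set is not taken from any single
fold: each feature's **inclusion frequency** — in how many of the
$10{,}000 \times 10$ fold-models it ranked in the top $k$ — is tallied,
and the $k$ most-included features (ties by mean rank, then probe id) are
refit on the full training cohort.

## Stage 5 — evaluation

`confusion_metrics()` counts CASE samples as positives and, by default,
CONTROL plus all `OTHER:` groups as negatives (benign-disease samples pool
with healthy controls into combined specificity; pass `negative_groups =
"CONTROL"` to report them separately). `roc_auc()` sweeps all distinct
vote-sum thresholds with a strict `>` rule and integrates by trapezoid,
which equals the tie-corrected concordance probability; it is checked in
the tests against brute-force pair counting and against pROC.
`stratified_positivity()` reports per-stage/per-group positivity panels,
and `cohort_compare()` produces the standard balance table (equal-variance
t-tests, Fisher's exact).

## The synthetic-cohort generator

Because real serum Ct matrices of this design are not publicly deposited,
the generator is a first-class component: every planted truth (informative
probes and their effect directions, stable probes, spike failures,
low-quality samples, sample offsets, the full probe population) is
returned alongside the data, so recovery can be asserted exactly.

The generative model: probe baselines $\mu_g \sim U(22, 30)$ with probe
SDs $\sigma_g \sim U(1, 3)$; designated stable probes have baselines
$U(20, 24)$ and SD 0.15; informative probes ($U(22, 28)$ baselines) are
shifted by $\pm\delta$ (default 1.5 cycles, half up / half down) in cases;
every sample carries a global offset $N(0, 0.5^2)$ modelling input-amount
variation (absorbed by the normalizer); Ct at or above the 40-cycle
ceiling is censored to undetected. Planted spike failures set the spike-in
to undetected; planted low-quality samples shift all endogenous probes by
+12 cycles so their 25th percentile crosses the limit — the two QC failure
modes are disjoint by construction. The probe population can be reused
across cohorts so training and validation share biology but not samples.

Default cohort sizes (150 cases + 50 controls, 3 spike failures, 5
low-quality samples split 7-in-case/1-in-control across the two filters,
22 calibrators, stage distribution 56/15/25/4%) mirror a realistic serum
miRNA study design and give the bookkeeping identity $200 - 3 - 5 = 192$
retained samples used by the acceptance checks.

The SD range $U(1, 3)$ was calibrated once, before the test suite was
frozen, so that a 1.5-cycle effect yields per-feature signal-to-noise near
0.3–0.5 — strong enough that a weighted-voting panel separates the groups,
weak enough that no single probe does; narrower noise made every cohort
trivially separable and the cross-validation curve flat.

## Reproducibility and determinism

All randomized stages (bootstrap, calibrator draw, CV partitions,
generator) draw seeds from named, deterministic substreams of a single
integer seed, so reruns are bit-identical, individual bootstrap replicates
or partitions can be reconstructed in isolation, and no stage perturbs
another's stream. Training runs carry a manifest with parameter
fingerprints; `run_validation()` refuses matrices scored under different
parameters.

## Limitations

- The generator draws probes independently given the sample offset; real
  miRNA panels are correlated, so synthetic classifier performance is
  optimistic relative to equally-sized real cohorts.
- Censoring is sharp at the ceiling; real qPCR shows stochastic dropout
  near the limit.
- Stability, S2N and the CV protocol assume two groups; multi-class
  designs are out of scope.
- At strongly reduced partition counts the argmin over the $k$ grid is
  noisy; chosen $k$ stabilizes as partitions grow toward the 10,000
  default.
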
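---
title: "Compact episignature classifiers: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compact episignature classifiers: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episig)
```

# The problem

Blood DNA-methylation episignatures are disease-specific patterns of
differential methylation at a defined CpG-site set, used as diagnostic
classifiers for Mendelian disorders of the epigenetic machinery (MDEM) such
as KMT2B-related dystonia and KMT2D-related Kabuki syndrome. Three practical
problems limit their use:

1. **Redundancy.** EWAS-significant site sets (often hundreds to > 1000
   CpGs) are heavily correlated; classifiers built on all of them carry
   redundant features with no accuracy benefit.
2. **Moderate effects and mosaics.** A classifier trained only on
   unambiguous loss-of-function carriers under-detects missense carriers,
   VUS carriers with intermediate methylation deviation, and mosaics, where
   only a fraction *d* of blood cells carries the variant.
3. **Erroneous mosaic calls.** Automated exome pipelines under-count
   variant reads for indels, producing variant allele fractions (VAF) far
   below 0.5 that masquerade as mosaicism.

`episig` addresses all three: bootstrap-ensemble mRMR compression of the
site set, stepwise re-training that recruits moderate-effect carriers into
the case set, and adjudication of suspected mosaics against in-silico
synthesized mosaic mixtures.

# Models and procedures

## Scales and preprocessing

All statistics operate on M-values, `M = log2(beta/(1-beta))`, the
variance-stabilised logit of the methylation fraction. QC follows array
practice: probes failing detection p-value (> 0.01), probe masks
(sex-chromosome, SNP-overlapping, cross-reactive) or per-probe call rate
(< 95%) are excluded; samples with mean detection p > 0.05 or call rate
< 95% are dropped. Sample outliers are screened with the 99% confidence
ellipse of the first two principal components of the centred M matrix:
a sample is outside when its squared Mahalanobis distance in PC1/PC2
(empirical covariance) exceeds the chi-square(2) quantile at 0.99. The
quantile family (chi-square vs F) and covariance estimator are not uniquely
determined by common usage; the chi-square form on the empirical PC
covariance is the package's default, and its 0.99 coverage is verified by
simulation in the test suite. Samples within 1% (relative, on the squared
distance) of the boundary are reported as `border`, making "within or at
the border" operational.

## EWAS and primary site selection

Per CpG, `fit_ewas()` regresses M on case/control status plus numeric
covariates (sex, age, estimated cell-type fractions) by OLS, testing the
status coefficient with a two-sided t-test. OLS was chosen as the default
because it is transparent and exactly checkable against the closed-form
two-sample t (the test suite does this); an optional moderated mode
(`moderated = TRUE`) shrinks residual variances empirically (via limma)
for small cohorts. Primary selection takes sites with `p < 5e-8` **and**
absolute raw between-group mean M difference `> 0.4`, both strict
inequalities, ordered by p. The 0.4 threshold is interpreted on the M
scale — the scale on which the EWAS itself is defined — and on the raw
(unadjusted) group difference; both choices are configurable because the
convention is ambiguous in the field.

## Gaussian mutual information and mRMR

Relevance and redundancy use the Gaussian mutual-information estimate

\[ MI(x, y) = -\tfrac{1}{2}\ln(1 - \rho(x, y)^2) \]

in nats, with \(\rho\) the Pearson correlation (point-biserial for the 0/1
phenotype). Classical greedy mRMR picks first the site with maximal
\(MI(x, y)\), then repeatedly the site maximising
\(MI(x_i, y) - \frac{1}{|S|}\sum_{j \in S} MI(x_i, x_j)\). The bootstrap
ensemble (`mrmr_ensemble_bootstrap()`) runs the greedy selection on *b*
class-stratified bootstrap resamples with per-run solution length *s* and
returns the union: redundant sites split votes across resamples while
independently informative sites recur, so the union compresses correlated
site sets far below the `b*s` bound.

Two details are deliberate choices where practice is silent: bootstraps are
stratified by class (with ~7 cases an unstratified resample can lose a
class entirely), and greedy ties break by ascending EWAS p-value, then site
ID, making selections deterministic and order-invariant.

## SVM, Platt scores, and stepwise re-training

`episignature()` fits a linear-kernel SVM (cost C, default 1.0, `e1071`)
on the M-values of the compressed site set, with inverse-frequency class
weights (the case:control ratio is typically ~7:19; configurable off) and
Platt sigmoid probability calibration fit by internal cross-validation,
which avoids optimistic calibration at small n. Scores are probabilities in
[0, 1]; the classification cutoff is 0.5 everywhere. Note that Platt's
smoothed targets bound training-case scores at \((n_+ + 1)/(n_+ + 2)\), so
with 7 cases even perfectly separated data cannot score above ~0.89 — a
property, not a defect.

`retrain_stepwise()` starts from the unambiguous case set, scores all
candidates, recruits those with score ≥ 0.5, and refits — by default
re-running the full chain (EWAS → selection → mRMR → SVM), since the
selected site set legitimately changes as the case set widens; a
`fixed_sites` mode refits only the SVM. Iteration stops at a fixed point,
a detected cycle (the case-set update is not guaranteed monotone), or
`max_iter`. Initial cases are retained unconditionally. The mechanism by
which re-training gains sensitivity is the widening of the effect-size
spectrum in the training set; the test suite verifies on planted allelic
series that the verified case set grows while specificity on held-out
controls stays ≥ 0.95.

## Classifier length sweep

`length_sweep()` varies `b` over 1..20 and `s` over 2..15 (280
configurations), records each configuration's realised episignature length
k, specificity on independent controls, and pseudo-sensitivity — verified
positives divided by the maximum verified positives over all
configurations — then averages per k. Plateau onset is the smallest k whose
window of 5 consecutive realised k values stays within `stability_tol`
(default 0.015, i.e. ≤ 1.5% deviation) of the window mean. The window
length is a package choice; 5 balances noise suppression against
resolution on the ~60 realised lengths of a typical sweep.

## Mosaic flagging, in-silico mosaics, and adjudication

For a heterozygous variant at depth n, the variant read count is
Bin(n, 1/2); the deviation of an observed count k from n/2 in binomial SD
units is \((k - n/2)/(\sqrt{n}/2)\). A case is a *potential mosaic* when
\(|k - n/2| > \sqrt{n}\) (2 SD), i.e. below the fraction
\(0.5 - 1/\sqrt{n}\). Table-reported VAFs use the equivalent
`deviation_from_vaf(n, vaf) = (vaf - 0.5) * 2 * sqrt(n)`. Read
re-examination corrections are `called + extra + noninformative/2`,
counting ambiguous reads half under unbiased allelic sampling.

In-silico mosaics mix an affected and an unaffected donor profile **on the
beta scale**, \(\beta = d\,\beta_a + (1-d)\,\beta_u\), with
\(d \sim U(0,1)\), then recompute M from the mixture (mixing is affine on
beta, not on M — a fixture test asserts the two orders differ). Each
mosaic receives a depth n from a lower-truncated normal (gene presets:
mean 184, SD 93, > 47; and mean 213, SD 121, > 14; rejection sampling,
strict inequality at the bound) and reads \(k \sim Bin(n, d/2)\). Training
variability is propagated by the leave-2-out ensemble: for every way of
removing 2 cases from the training set (21 for 7 cases), a classifier is
fit on the reduced set without any stepwise recruitment and the left-out
cases join the affected donor pool. With 150 mosaics per combination this
yields 3150 scored mixtures.

`build_band()` pools up to 3000 mosaics (the pooled-across-ensembles
reading of the procedure; per-ensemble banding would leave ~7 mosaics per
bin), bins their scores in 0.025-wide bins of realised variant read
fraction k/n (the observable axis, not d/2), computes 5th/95th score
quantiles per bin (empirical type-7 quantiles throughout the package), and
smooths them with loess (span 0.75, degree 2 — R's defaults; the span is a
parameter because loess dialects differ across implementations). The
smoothed lower band is clipped to the upper band. `adjudicate()` scores
each suspect with all ensemble members, reports the mean with a t-based
95% CI (mean ± t(0.975, m−1)·SD/√m over the m classifiers — the CI family
is unstated in common practice, and the t form is the standard
small-sample default), and calls `above_95` when the mean exceeds the
smoothed 95th-percentile band at the suspect's VAF: the sample looks too
constitutive for its reported read fraction, the signature of an erroneous
(under-counted) variant call. Fractions outside the band support evaluate
at the nearest endpoint with a warning.

## Severity and age at onset

`mean_norm_meth_deviation()` is the mean over episignature sites of
|z|, where z standardises the sample's M-value against the control mean
and SD (n−1 denominator) at that site. The control reference defaults to
the training controls — the statistic is defined against the controls the
classifier knew — but the control set is an argument. For control-like
samples the statistic approaches \(E|N(0,1)| = \sqrt{2/\pi} \approx
0.798\), inflated by \(\sqrt{1 + 1/n}\,E|t_{n-1}|/E|N(0,1)|\) when the
reference has only n controls; the tests use this exact finite-n oracle.
Association with age at onset uses Cox proportional-hazards regression
(Breslow ties, `survival`), right-censoring carriers without onset at
examination, tested by likelihood ratio; `correlation_with_proxy()`
substitutes examination age for censored onsets to report a Pearson r and
r².

# The synthetic cohort generator

`simulate_cohort()` emulates the study design that the methods target:
19 controls, 7 full-effect initial cases, and a candidate group with
per-sample severity multipliers u (allelic series) and mosaic degrees d.
Baseline betas come from a three-component mixture (hypo ~0.1, hemi ~0.5,
hyper ~0.9) — the bimodal shape of array methylation — jittered and
perturbed on the M scale. Carriers shift by `u * effect_delta` at the
planted signature sites (sign alternating across sites), plus covariate
terms (sex, age, two cell-fraction columns with confounding-scale slopes)
and Gaussian noise (SD 0.5 M). Mosaic carriers are produced by the same
beta-scale mixing rule as the in-silico mosaics, so generator and
evaluator are internally consistent. Variant reads follow the same
truncated-normal/binomial model, with optional injected "erroneous calls"
whose reported counts are deflated by a stated fraction. One master seed
fans out to per-component child seeds; outputs are bit-identical given the
seed.

Default sizes (2000 sites, 100 signature sites, effect 4 M units) are
desk-scale: large enough that the planted signature dominates noise the
way a genome-wide-significant episignature dominates an EWAS, small enough
for fast simulation; the test suite uses 300–800 sites with the
significance threshold relaxed to 1e-5/1e-6 accordingly, since the
genome-wide 5e-8 presupposes ~850k tests. The severity distribution of
real allelic series is unknown; u is a modelling choice exposed in the
configuration (uniform on [0.3, 1] by default, or an explicit vector),
not an estimate.

What the generator does **not** emulate: probe-level chemistry noise and
batch effects, realistic genome-wide correlation structure (sites are
independent given the signature), genotype complexity beyond one causal
variant, and population stratification. Passing tests therefore
demonstrate correctness of the algorithms under the stated generative
model, not clinical performance on real arrays.

# Numerical choices

- Selection thresholds are strict inequalities (`p < `, `|diff| > `).
- Constant CpG sites are flagged (effect 0, p 1), never dropped silently.
- MI of a constant vector is 0 with a warning; |rho| = 1 caps MI at
  −ln(1e−12)/2 with a warning.
- Quantiles are empirical type-7 (linear interpolation) everywhere.
- Truncated-normal depths are drawn by rejection — exact at desk scale —
  rounded to integers, strictly above the truncation bound.
- The serialised model artifact stores the linear weights and Platt
  constants in plain text; `score_model_artifact()` reproduces in-memory
  scores to ~1e-15 (the sign convention of the calibration constants is
  resolved against the fitted model at write time).
- All list-valued randomness derives from one seed via
  `sample.int(.Machine$integer.max - 1)` child seeds.

# Known limitations

- With very small case sets Platt calibration is coarse; scores cluster
  away from 0/1 and the 0.5 cutoff is the only supported decision rule.
- The greedy mRMR is not globally optimal (that is the point of the
  ensemble variant, which improves but does not guarantee optimality).
- Cycle detection in re-training stops infinite alternation but keeps the
  last fitted model, not a consensus of the cycle.
- The loess band is undefined outside the observed fraction range;
  endpoint evaluation is a pragmatic extrapolation, flagged by warning.
- The Cox fit assumes proportional hazards for the severity statistic;
  with < ~8 events the likelihood-ratio p is approximate.

# Problem sizes used by the tests

Unit and property tests run on 300–800-site cohorts with 26–47 samples;
the ensemble-combinatorics checks run the full 21-combination leave-2-out
ensemble (150 mosaics each, 3150 total) and the full 280-configuration
length sweep on an 800-site cohort; null-calibration checks use 4000–8000
sites or 500 replicates. The whole suite runs in about a minute on one
CPU.
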
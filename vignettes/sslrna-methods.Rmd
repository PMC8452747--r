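---
title: "Methods: SSL-RNA profiling and stacked discrimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SSL-RNA profiling and stacked discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sslrna)
```

This vignette documents the statistical models, conventions, and design
choices behind `sslrna`, in the spirit of the long-form methods sections
that accompany differential-expression packages. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The problem

Skin-surface-lipid RNA (SSL-RNA) is mRNA recovered from sebum with an
oil-blotting film and profiled with a targeted amplicon panel of roughly
20,000 human transcripts. The material is scarce and degraded, so two
failure modes dominate: whole samples with very few detected genes, and
genes detected in only a subset of samples. Downstream, the scientific
questions are (i) which genes differ between Parkinson's disease (PD)
cases and controls, and (ii) whether the expression profile, together with
age and sex, can discriminate cases from controls — with disease severity
(Hoehn & Yahr stage, H&Y) as an auxiliary signal.

## Quality control

Two rules, applied in order:

* **Samples**: keep samples whose *Targets Detected* fraction — the share
  of panel genes with read count at least `detect_min` (default 1) — is
  strictly greater than 20%.
* **Genes**: among the retained samples, keep genes with non-zero counts
  in strictly more than 90% of samples.

Both thresholds are strict inequalities, and gene presence is recomputed
after sample removal, so the order matters. The vendor definition of
"detected" is not public; `detect_min = 1` (any non-zero count) matches
the gene filter's own convention and is exposed as a knob. Filtering is
idempotent, and every QC report partitions the input into kept and dropped
IDs with the triggering metric recorded.

## Normalization, transform, PCA

Size factors use the median-of-ratios estimator: with reference genes
restricted to those with positive counts in every sample,

$$ s_j = \operatorname{median}_{g} \frac{k_{gj}}{(\prod_{j'} k_{gj'})^{1/n}}. $$

The median is taken over the ratios themselves (linear scale). Two
conventions are worth noting. First, with an even reference-set size this
differs from taking the median of log-ratios (arithmetic versus geometric
averaging of the middle pair); the package's tests pin the linear
convention against a brute-force oracle and cross-check against an
independent implementation at odd reference sizes, where the two coincide.
Second, size factors are defined only up to a common scale: multiplying one
sample's counts by $c$ also moves every per-gene geometric mean by
$c^{1/n}$, so it is factor *ratios* that scale by exactly $c$, and the
package's equivariance tests assert that form.

The variance-stabilizing transform is `log2(k/s_j + 1)`. This is a
deliberate simplification: the transform feeds PCA and heatmaps only, and
any monotone variance-compressing transform preserves the pipeline's
qualitative behavior; the parametric dispersion-fitted VST of dedicated DE
packages is out of scope here. Count 0 maps to 0 for any size factor and
the transform is invariant to jointly rescaling counts and factors.

PCA takes the `n_top = 1000` genes by row variance (ties broken by gene
ID), centers genes without scaling (the log transform already stabilizes
scale), and fixes each component's sign so its largest-magnitude loading
is positive — otherwise scores are reproducible only up to sign. Gene-wise
z-scores for heatmaps use the sample standard deviation (divisor $n-1$);
constant genes map to zero rather than NaN.

## Negative-binomial likelihood-ratio test

Counts are modeled as negative binomial with
$\mathrm{Var} = \mu + \alpha\mu^2$ and log link with offset $\log s_j$.
Per gene, the full model (intercept + group) is tested against the reduced
model (intercept) by $2(\ell_\text{full} - \ell_\text{reduced}) \sim
\chi^2_1$; the log2 fold change is the group coefficient in log2 units.

The dispersion convention required care. A plain per-gene dispersion MLE
is biased low at realistic group sizes, and because low $\hat\alpha$
inflates the statistic, the test becomes noticeably anti-conservative
(measured rejection ≈ 0.058 at nominal 0.05 for n = 20/20, α = 0.1 —
whether the MLE is taken under the full model or freely in each model).
The package therefore estimates $\hat\alpha$ by maximizing the Cox–Reid
adjusted profile likelihood under the *reduced* model, floored at 1e-8,
and holds it fixed for both fits. Estimating under the null keeps
$\hat\alpha$ from absorbing the tested contrast, and the Cox–Reid term
corrects the degrees-of-freedom bias; the measured null rejection rate
then sits at the nominal level (the acceptance suite checks the 99%
binomial band around 0.05 on 2000 null genes). The trade-off is mild
conservatism for genes with very large true effects, where the null-model
dispersion is inflated by the group difference; the power check in the
test suite (planted log2FC = 1, n = 50/50, power > 0.8 at FDR 0.05) shows
this costs little. No empirical-Bayes shrinkage across genes is applied — DE calls
here are validated by calibration properties, not by matching any specific
cohort's DEG counts.

Mean fits use Fisher scoring on the log scale (the two-group design makes
each group a one-dimensional problem); non-convergent genes are reported
with p = 1 and a `converged = FALSE` flag, never dropped. The Methods'
"p < 0.05" screen is kept as a reporting flag (`passed_p_005`) next to the
BH-FDR flags rather than as a pre-filter before adjustment, since BH over
all tested genes is the defensible default. Multiple testing uses
Benjamini–Hochberg step-up (strict thresholds 0.05 and 0.25 for calling);
the DEG-overlap Fisher test is one-sided (enrichment), with the odds ratio
reported as the 2×2 cross-product ratio.

## The stacked discrimination model

**Feature filter.** Gene $g$ enters the model if its detection rate
$d_g = N_{g,m}/N$ — the fraction of samples whose count strictly exceeds
the lower bound $m$ — is strictly greater than a threshold $t$, both
computed on training samples only. $m$ and the hyperparameter-search
"minimum read count" are treated as the same integer knob.

**Rank normalization.** Within each sample, genes are ranked in descending
order of expression (rank 1 = highest, ties averaged); within each gene,
ranks are min-max scaled to [0, 1] using the minimum and maximum observed
on the training samples, with held-out samples transformed by the fitted
min/max and clipped. Constant-rank genes map to 0.5. Per-sample ranking
makes the features exactly invariant to any strictly increasing
per-sample transform — including size-factor division — so ranking raw
counts and ranking normalized counts are the same operation. Whether the
original analysis fitted the min/max on training samples only is
ambiguous; this package fits on training only, the leakage-safe choice,
and verifies it with a label-permutation null (mean test AUC must stay in
[0.35, 0.65]).

**Stacking.** Both learners are extremely-randomized-trees ensembles
(random split thresholds, no bootstrap resampling; `ranger` with
`splitrule = "extratrees"`). The H&Y stage regressor maps the rank
features plus age and sex to a continuous stage; controls are assigned
stage 0 so every sample has a target (early-PD cohorts genuinely contain
stage-0 patients). The classifier sees the same features plus a
predicted-stage column and returns a PD probability. How the original
design obtained stage predictions for classifier *training* is not
specified; this package uses K-fold (default 10) out-of-fold regressor
predictions on the training set — the full-train regressor would hand the
classifier optimistically accurate stages (for PD cases, stage > 0 almost
surely) and let label information leak through the stacked feature. At
prediction time the full-train regressor supplies the stage. Age enters
in raw years and sex as a 0/1 indicator (male = 1).

**Hyperparameters.** Seven knobs are shared by both ensembles: $t$, $m$,
number of trees, maximum depth, fraction of features per split, minimum
samples per leaf, and minimum samples to split. Defaults
(`default_hyperparams()`): t = 0.9, m = 1, 300 trees, unlimited depth,
0.3 features per split, leaf 1, split 2 — ordinary ERT settings with the
detection filter matching the QC presence scale. `tune_hyperparameters()`
optimizes them by seeded random search (default spaces in
`default_search_space()`) scored by stratified 10-fold cross-validated
AUC of the whole pipeline re-fitted inside each fold; a Bayesian
optimizer would share the contract, but seeded random search is
deterministic and dependency-free.

**Evaluation.** The combined cohorts are split stratified into training
and test sets (fraction 81/116 by default, mirroring a 116-sample
two-cohort study). Training repeats over five seeds; each repetition
reports trapezoidal ROC AUC plus sensitivity, specificity, precision, and
F1 at probability threshold 0.5 (the operating point is otherwise
unspecified), aggregated as mean ± SD, together with the ablation model
without the predicted-stage feature.

## The synthetic-data generator

`simulate_cohort()` draws negative-binomial counts with a single global
dispersion (default α = 0.1, a typical bulk-RNA-seq value), gene baseline
means log-uniform between 5 and 500 reads, and log-normal library sizes
with CV 0.3. A planted set of genes (default 25 up + 25 down) is shifted
in cases by `log2fc + stage_slope × stage` in log2 units (defaults 1 and
0.25). Case H&Y stages are drawn from {0, 1, 2} with probabilities
(0.04, 0.40, 0.56) — the composition of a 50-case medicated male cohort
with stages 0 (2), I (20), II (28) — and controls are stage 0. A fraction
of samples (default 10%, matching the reported exclusion rate at data
cleaning) is flagged low-quality: after sampling, each of their gene
counts is independently zeroed with probability 0.9, leaving them near
10% Targets Detected, below the 20% QC threshold. No quantitative profile
of the real excluded samples exists, so the dropout parameters are free
knobs chosen to reproduce the failure mode, not calibrated values.
`simulate_two_cohorts()` yields a 15+15 mixed-sex cohort and a 50+50 male
cohort sharing one panel and one planted gene set. Levodopa dose for cases
is loosely proportional to stage (≈150 mg/day per stage plus noise) so
dose-correlation screens face a realistic confounder.

What the generator does *not* emulate: amplicon/GC bias, batch effects,
per-gene dispersion variation, correlated gene modules, or any real
cohort's parameter values. Tests passing on these simulations therefore
demonstrate the pipeline's statistical correctness and leakage-freedom,
not clinical performance; headline numbers from the motivating study
design (e.g. a specific AUC) require the original data and are explicitly
not reproduction targets.

## Numerical and reproducibility choices

* All randomness flows from explicit integer seeds; the simulator and
  fold assignments save and restore the caller's RNG state. `ranger` runs
  single-threaded with a fixed seed, so fitted ensembles and predictions
  are bit-reproducible.
* The pipeline derives per-stage seeds as `seed + stage index`, writes
  all tabular artifacts as TSV and structured ones as JSON, and
  checksums everything into `manifest.json`; two runs with the same
  config produce byte-identical artifacts.
* Degenerate inputs have defined behavior: all-equal counts give LRT
  statistic 0 and p = 1; constant genes z-score to 0 and rank-scale to
  0.5; empty QC or feature selections raise explicit errors naming the
  remedy; single-class test sets refuse to compute AUC.
* Problem sizes in the test and acceptance runs (2000-gene panels,
  20–50 samples per group, 5–10 evaluation seeds) were chosen as the
  smallest sizes at which the statistical properties under test are
  stable.

## Known limitations

The DE module handles the two-group design only (no additional
covariates, no outlier moderation). The dispersion is global in the
simulator and per-gene-estimated in the test, so simulated data are
slightly "easier" than real panels with dispersion trends. Rank features
discard magnitude information by construction; genes whose biological
signal lies in overall abundance shifts smaller than one rank step are
invisible to the classifier. The stage regressor treats H&Y as a
continuous target, which is standard but ignores its ordinal geometry.
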
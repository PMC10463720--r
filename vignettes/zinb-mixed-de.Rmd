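---
title: "Subject-aware differential expression for multi-subject scRNA-seq: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subject-aware differential expression for multi-subject scRNA-seq: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Droplet scRNA-seq studies that compare two groups of subjects (e.g. patients
versus controls) face two confounders at once. First, *dropout*: a gene
moderately expressed in a cell can be observed as a zero because the
transcript was not captured, inflating the zero count beyond what a count
distribution explains. Second, the *subject effect*: cells of one person
cluster away from another person's cells of the same type, so thousands of
cells are far from thousands of independent observations — methods that
ignore this pseudo-replication reject wildly under the null. This package
fits, per gene, a zero-inflated negative binomial mixed model that addresses
both, and tests the group effect with a Wald statistic.

## The model

For gene $k$ (index suppressed below), cell $j$ of subject $i$ with group
label $X_i \in \{0,1\}$ and sequencing depth $S_{ij}$ (the cell's total UMI
count):

$$Y_{ij} \sim \pi_{ij}\,\mathbb{I}\{Y_{ij}=0\} +
  (1-\pi_{ij})\,\mathrm{NB}(S_{ij}\lambda_i,\, d),$$
$$\log \lambda_i = \alpha + \beta X_i + \gamma_i,\qquad
  \gamma_i \sim N(0, \sigma^2),$$
$$\mathrm{logit}\,\pi_{ij} = \mathrm{logit}\,\pi^0 +
  \theta\,\mathbb{I}\{Y_{ij}=0\} + \eta_i,\qquad
  \eta_i \sim N(0, \tau^2).$$

The NB is parameterized by mean $\mu$ and dispersion $d$ with variance
$\mu + \mu^2/d$ (the `nbinom2` convention; larger $d$ means closer to
Poisson). $\beta$ is the log fold change between groups and the target of
inference; $\gamma_i$ and $\eta_i$ are subject random intercepts carrying
the between-subject variation in expression and in dropout.

The baseline dropout rate $\pi^0$ is *not* estimated per gene in isolation.
Dropout probability falls with expression level, so the package pools
information across genes: it computes each gene's zero proportion, fits a
LOESS curve of those proportions against the log of the gene-level mean
log-normalized expression, and reads every gene's $\pi^0$ off the fitted
curve (`fit_dropout_curve()`, `predict_pi0()`). The curve value is then
plugged into the per-gene model as known (two-stage estimation; its
uncertainty is not propagated). $\theta$ lets the dropout rate at an
*observed zero* deviate from this pooled initial estimate.

### The zero-observation deviation is a boundary parameter

Because $\theta$ enters only through observations that are already zero, the
two-branch likelihood is a quasi-likelihood rather than a proper generative
density, and its $\theta$-profile is monotone: the optimizer drives
$\hat\theta$ to its upper bound (the package caps it at 15, where the
zero-branch dropout probability is saturated to within $10^{-6}$), and
$\tau^2$ then drifts along a flat ridge. This is a property of the model,
not of the optimizer — the same construction expressed in `glmmTMB`
(zero-inflation formula with a zero-indicator covariate and a fixed
$\mathrm{logit}\,\pi^0$ offset) lands in the same place, with the same
$\hat\beta$ and $\mathrm{se}(\hat\beta)$ to three decimals. Inference on
$\beta$ is unaffected: the information matrix is block-stable, and the
package drops saturated/flat coordinates (with a `boundary` flag) before
inverting the observed information. Fitted $\theta$ and $\tau^2$ values
should not be interpreted substantively.

## Estimation and testing

Per subject, the pair $(\gamma_i, \eta_i)$ is integrated out on standardized
scales by a joint two-dimensional Laplace approximation: an inner damped
Newton ascent with analytic gradient and Hessian finds the conditional mode;
termination is gradient-based (infinity norm $<10^{-9}$) because near the
optimum objective *differences* sink below double precision long before the
gradient does, and the marginal likelihood must be reproducible to ~1e-10
regardless of warm starts. Adaptive Gauss–Hermite quadrature (`aghq`, any
node count) and plain Monte Carlo are included for validation; on small
problems Laplace agrees with dense-grid quadrature to ~1e-5 relative and
AGHQ-15 to ~1e-13 (tested).

The outer problem maximizes the summed subject marginals over
$(\alpha, \beta, \log\sigma^2, \theta, \log\tau^2, \log d)$ with L-BFGS-B
(relative objective tolerance $\approx 2\times 10^{-9}$, projected gradient
$10^{-5}$, up to 3 jittered restarts, seeded). Initial values come from
group-wise depth-normalized rates; variances start at 0.1 and $d$ at 1.
Variances may hit their $10^{-8}$ lower bound (flagged, allowed). The Wald
statistic is $z = \hat\beta/\mathrm{se}(\hat\beta)$ with
$\mathrm{se}$ from the central-difference observed information at the
optimum, referred to a standard normal — the choice of reference follows the
Wald construction; no $t$ correction is applied.

`run_idesc()` orchestrates: the 5%-of-cells gene filter (genes at exactly
5% are kept), the 5-cells-per-subject filter (subjects at exactly 5 kept),
depth computation, log-normalization
($\log(1 + \mathrm{count}/S \times 10^4)$ — the field's standard transform;
the scale factor is configurable), the pooled dropout curve, then one fit
and Wald test per gene. Genes whose fit fails are reported with a status
code, never silently dropped, and are never called DE.

### Sequencing depths for gene panels

For full-transcriptome matrices the depth $S_{ij}$ is the column sum of the
counts (computed after gene filtering by default; configurable). For
matrices that cover only a small panel — notably simulated datasets, where
the generating depths are the cells' transcriptome-wide totals — column
sums of the panel are *not* the sequencing depths: if a third of panel genes
are upregulated in one group, panel sums absorb part of the effect into the
offset and bias every $\hat\beta$ down (we measured ≈ −0.15 with 50 of 150
genes DE at $\beta = 0.4$). `run_idesc()`, `estimate_reference_params()`
and `permutation_type1()` therefore accept known depths, and
`simulate_dataset()` returns the depths it generated with; the evaluation
harness passes them through.

## The simulator

`simulate_dataset()` reproduces the reference-driven generative process used
for the type-I-error and power studies. Reference parameters — per-subject
dropout rates $\hat\pi_{ik}$, relative expression $\hat\lambda_{ik}$,
per-gene dispersion $\hat d_k$, and per-subject depth pools — come either
from `estimate_reference_params()` (a per-gene fixed-effect ZINB fit with
subject-specific $(\pi_i, \lambda_i)$ and shared $d$, profiled over
$\log d$) or from `make_synthetic_reference()`, which draws them so that no
external dataset is needed: log-normal expression with subject jitter,
dispersions around 1, and dropout rates following a decreasing logistic
trend in log expression, centred above $1/2$ as in real droplet data.

Counts are drawn as
$Y \sim \pi\,\mathbb{I} + (1-\pi)\,\mathrm{NB}(S\hat\lambda e^{\beta
\mathbb{I}\{\mathrm{group}\,2\}}, d)$ with cell-level
$\mathrm{logit}\,\pi \sim N(\delta \cdot \mathrm{logit}\hat\pi,
\sigma^2_\pi)$. The study conditions are the defaults: $d = 1$,
$\sigma^2_\pi = 2000$, 450 genes (150 DE, 300 non-DE) selected under the
moderate-to-high expression rule $\hat\lambda_{ik} \ge 1/S_{ij}$, depths
drawn *without replacement* from the subject's pool (with replacement, with
a warning, only if the pool is too small), $m \in \{20, 50, 100\}$ cells
per subject and $\beta \in \pm\{0.1, \dots, 0.7\}$ across datasets.
$\sigma^2_\pi = 2000$ is extreme on the logit scale — cell-level dropout
indicators become nearly Bernoulli with subject-level success probability
$\Phi(\delta\,\mathrm{logit}\hat\pi / \sigma_\pi)$ — and is kept because it
is the stated study condition; it is a config field, not a constant.

Two design points deserve note. *Capture efficiency:* $\delta$ multiplies
the dropout logit, so its direction depends on where the reference dropout
rates sit; with rates mostly above $1/2$ (the realistic regime the synthetic
reference emulates), $\delta = 0.5$ is the high-capture setting with the
fewest zeros and $\delta = 1.5$ the low-capture setting with the most.
*Design:* the original protocol simulates, for each of 30 base subjects,
one sample in *each* group (sharing that subject's parameters) —
`paired = TRUE`. The default is the scaled unpaired design (30 subjects
split 15/15) used by all desk-scale checks here; both are available.

Per-gene RNG substreams (dropout draws, group-1 counts, group-2 counts,
derived deterministically from one seed) make datasets bit-reproducible and
guarantee that changing $\beta$ alters only the group-2 counts of DE genes.

## Evaluation tools

- `permutation_type1()`: permutes subject group labels (never cells,
  preserving group sizes), reruns the full pipeline per permutation, and
  reports each gene's rejection fraction at the nominal level. The
  published calibration band for the median rate at $\alpha = 0.05$ over
  500 permutations is 0.031–0.069; the package's desk-scale check (20
  genes × 200 permutations, one seeded null dataset) computes the same
  median, and the acceptance script recomputes it at run time.
- `sens_spec()`, `roc_auc()`: threshold metrics and the rank (Mann–Whitney)
  AUC with ties averaged; missing p-values count as non-significant
  (conservative).
- `fisher_overlap()`, `jaccard()`: between-dataset consistency of DE lists.
  The Fisher test is one-sided enrichment (overlap significance is an
  enrichment question); the universe is the caller's choice — the CLI uses
  the intersection of tested genes, a documented default rather than a
  claim about any published analysis.
- `effect_coefficients()`: per-cell dot product of log-normalized expression
  with the estimated group effects over chosen DE genes, scaled to maximum
  absolute value 1; visualizes within- and between-subject variation in the
  group signature.

## What the synthetic generator does and does not emulate

It reproduces the features the model and the evaluation design depend on:
depth heterogeneity within and between subjects, a dropout–expression
S-curve with subject-level spread, between-subject expression variation,
NB overdispersion around $d = 1$, and the expression-eligibility rule. It
does not emulate cell-type mixtures, doublets or ambient RNA, batch
structure beyond the subject level, gene–gene correlation, or any
particular study's estimated parameter values — only the distributional
shape. Passing checks on
simulated data therefore demonstrate calibration and power *under the
model's intended regime*, not robustness to annotation errors or QC
artifacts, which are upstream concerns.

## Problem sizes and numerical choices

Desk-scale defaults keep every check reproducible on one CPU: the
calibration check uses 20 genes × 200 permutations at $n = 30$, $m = 50$;
the specificity check 150 genes (50 DE / 100 non-DE); parameter recovery
100 replicates at $n = 30$, $m = 100$; power grids $m \in \{20, 50, 100\}$
and $\beta \in \{0.1, 0.4, 0.7\}$ at 80 genes per setting. LOESS uses span
0.75, degree 2, predictions clipped to $[10^{-4}, 1-10^{-4}]$ so
$\mathrm{logit}\,\pi^0$ is always finite; out-of-range queries are clamped
to the training range rather than extrapolated. The dropout-curve x-axis is
the log of the gene-level mean log-normalized value; the variant without
the outer log is available (`expression_axis = "mean"`) since axis
conventions differ across displays — the two are never mixed.

## Known limitations

- $\hat\theta$ and $\hat\tau^2$ are boundary/ridge quantities (above); only
  $\beta$, $\sigma^2$, $d$ and the Wald test are interpretable outputs.
- $\pi^0$ is plugged in as known; its smoothing uncertainty is ignored.
- The Wald test uses a normal reference; with very few subjects per group
  expect the usual mild anti-conservatism of Wald tests in mixed models.
- No shrinkage or empirical-Bayes moderation of $d$ across genes.
- Only a binary group effect with subject random intercepts is supported —
  no additional covariates, likelihood-ratio or score tests.
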
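# idesc

Cell-type-specific differential expression between two groups of subjects in
multi-subject droplet scRNA-seq data.

Comparing patients to controls at the level of single cells runs into two
problems at once: **dropout** (a moderately expressed gene observed as zero
because its transcripts were not captured) inflates zeros beyond any count
distribution, and the **subject effect** (cells of the same person are
correlated) makes thousands of cells far fewer than thousands of independent
observations. Methods that ignore either one reject wildly under the null or
lose power. `idesc` fits, per gene, a zero-inflated negative binomial mixed
model that handles both.

## The model

For gene *k* (subscript dropped), cell *j* of subject *i* with group label
*X<sub>i</sub>* ∈ {0, 1} and sequencing depth *S<sub>ij</sub>*:

```
Y_ij ~ pi_ij * I{Y_ij = 0} + (1 - pi_ij) * NB(S_ij * lambda_i, d)
log(lambda_i)  = alpha + beta * X_i + gamma_i,   gamma_i ~ N(0, sigma^2)
logit(pi_ij)   = logit(pi0) + theta * I{Y_ij = 0} + eta_i,  eta_i ~ N(0, tau^2)
```

with the negative binomial parameterized by mean mu and dispersion d
(variance mu + mu²/d). `beta` is the log fold change between the groups.
The baseline dropout rate `pi0` is pooled across genes: a LOESS curve of
per-gene zero proportions against expression level, read off at each gene
(`fit_dropout_curve()` / `predict_pi0()`). Subject random intercepts
(`gamma`, `eta`) absorb between-subject variation in both components. The
random effects are integrated out by a joint 2-D Laplace approximation
(compiled; adaptive Gauss–Hermite and Monte Carlo integrators included for
validation), the likelihood is maximized by quasi-Newton, and H0: beta = 0
is tested with a Wald statistic. See the methods vignette
(`vignettes/zinb-mixed-de.Rmd`) for assumptions, numerical choices and
limitations.

The package also ships the matching simulation engine (`simulate_dataset()`
with synthetic or data-estimated reference parameters) and the evaluation
harness: permutation-based empirical type I error, sensitivity/specificity/
AUC, Fisher overlap tests, Jaccard indices, and per-cell effect
coefficients.

## Worked example

```r
library(idesc)

# a reference-parameter set (no external data needed) and a small dataset:
# 10 subjects (5 vs 5), 30 cells each, 6 DE genes among 24 at log FC 0.6
ref <- make_synthetic_reference(seed = 1)
cfg <- simulation_config(n_subjects = 10, m = 30, beta = 0.6, delta = 1,
                         n_de = 6, n_null = 18, seed = 2)
sim <- simulate_dataset(ref, cfg)
sim$cm
#> count_matrix: 24 genes x 300 cells, 10 subjects (5 | 5)

tbl <- run_idesc(sim$cm, idesc_config(seed = 3), depths = sim$depths)
head(tbl[order(tbl$p_value),
         c("gene_id", "beta", "fold_change", "se_beta", "p_value",
           "sigma2", "d", "pi0")], 5)
#>  gene_id  beta fold_change se_beta  p_value   sigma2    d   pi0
#> gene0205 0.814        2.26   0.160 3.85e-07 6.28e-08 1.19 0.526
#> gene0111 0.718        2.05   0.158 5.31e-06 7.12e-03 1.33 0.526
#> gene0083 0.731        2.08   0.161 5.61e-06 1.93e-07 1.22 0.535
#> gene0121 0.704        2.02   0.174 5.09e-05 7.53e-03 1.44 0.597
#> gene0284 0.495        1.64   0.144 6.01e-04 3.50e-08 1.43 0.543

de <- call_de(tbl, alpha = 0.01)
table(called = tbl$gene_id %in% de,
      truly_de = tbl$gene_id %in% sim$truth$gene_id[sim$truth$is_de])
#>        truly_de
#> called  FALSE TRUE
#>   FALSE    18    0
#>   TRUE      0    6
```

Each row of the results table is one gene: `beta` is the estimated log fold
change of group 2 over group 1 (`fold_change = exp(beta)`), `se_beta` its
Wald standard error, `p_value` the two-sided normal p-value, `sigma2` the
between-subject expression variance, `d` the NB dispersion, and `pi0` the
pooled baseline dropout rate plugged into the fit. Here the top-ranked genes
are exactly the simulated DE genes (true log FC 0.6): at p < 0.01 all 6 are
called with no false positives. `depths = sim$depths` supplies the
generating transcriptome-wide depths, since column sums of a 24-gene panel
are not sequencing depths.

A thin command-line interface over the same functions is installed at
`system.file("cli", "idesc", package = "idesc")` with subcommands `fit`,
`simulate`, `permute`, `evaluate` and `dropout-curve`; every output is
accompanied by a `.config.json` echo for reproducibility.

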
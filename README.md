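# rpcascade

Cascaded rescoring of sparse pairwise interaction predictions using
reciprocal-perspective context features.

## What it does, and for whom

Integrative predictors of miRNA–gene targeting (and similar bipartite
interaction problems) emit one confidence score per pair, and downstream
users call interactions with a single global threshold. That ignores how
differently scores are distributed from one miRNA, or one gene, to the
next: a score that is exceptional in one entity's context is noise in
another's. `rpcascade` is for computational biologists who have such a
score table plus a list of validated interactions and want a refined
ranking that exploits this per-entity context — including the recovery of
putative false negatives the original predictor scored near zero.

## The method

For every entity the package builds its **One-to-All (O2A) curve** — all
scores involving it, rank-ordered descending, with ranks expressed as
percentiles in [0, 1] so different curve sizes are comparable — and
estimates a **local baseline**: on dense curves (n > 100) the knee of the
LOESS-smoothed curve found by the Kneedle algorithm, on sparse curves
(n ≤ 100) the score median. For a pair (X, Y) with raw score *m*, the
thirteen context features are the pair's percentile ranks *rxy*, *ryx* in
each perspective, their reciprocal product *ARRO* = (1−rxy)(1−ryx), each
baseline's cutoff percentile and score (*rxt*, *sxt*, *ryt*, *syt*), the
percentile differences *pdx* = rxt − rxy, *pdy* = ryt − ryx, the fold
differences *fdx*, *fdy* of *m* from each cutoff score, and the
standardized distances *stdx*, *stdy* of *m* from each curve's mean.

A second-stage classifier — gradient-boosted trees (learning rate 0.3,
max depth 6, 200 rounds, early stopping 5) or a random forest (100 trees,
depth 19, 4 features per split) — is trained on these features plus *m*,
with validated positives against uniformly sampled unvalidated pairs as
balanced presumed negatives, and a recency-based train/test split.
Refined and original scores are compared by paired stratified bootstrap
of ROC/PR AUC with Welch's t-test; the **Difference of Scores**
(DoS = refined − original) with a DoS ≥ 0.5 filter surfaces candidate
false negatives, and refined scores are tiered by the cumulative
top-1/5/10/33% / bottom-66% convention.

A synthetic-data generator plants exactly the reciprocal structure the
method exploits (per-entity baseline offsets, a high-scoring head per
curve, lifted positives, a recency tag), so the whole pipeline is
testable without external downloads.

## Worked example

```r
library(rpcascade)

sim <- generate_synth(synth_config(seed = 7))   # 60 x 400 grid, density 0.6
sim$table
#> <score_table> 14400 pairs, 60 A-entities, 400 B-entities

res <- rp_rescore(sim$table, sim$labels, n_boot = 200, seed = 7)
res$report
#> <boot_auc> 200 iterations
#>      model roc_auc_mean roc_auc_sd pr_auc_mean pr_auc_sd
#> 1  refined       0.9048    0.01302      0.8635   0.02265
#> 2 original       0.6674    0.02128      0.6354   0.02395
#> Welch p (ROC): 4.09e-290   Welch p (PR): 7.04e-280

head(res$test_scores[order(-res$test_scores$dos), ], 3)
#>             a         b label    original   refined       dos
#> 174 mirna_060 gene_0350     1 0.015159789 0.9699042 0.9547444
#> 143 mirna_024 gene_0015     1 0.007047645 0.9583526 0.9513050
#> 204 mirna_060 gene_0097     1 0.011830950 0.9557612 0.9439302
```

The bootstrap table says the cascade lifts held-out ROC AUC from 0.67 to
0.90 on data whose per-entity baseline shifts confound the raw score; the
Welch p-values say the paired bootstrap distributions are far apart. The
three listed pairs are planted true interactions the "original" predictor
scored near 0.01 but the cascade recovers at ~0.96 — the DoS ≥ 0.5
discovery pattern.

A command-line front end mirroring the R functions ships in
`inst/cli/rpcascade` (subcommands `simulate`, `baselines`, `features`,
`train`, `predict`, `evaluate`, `rank`).

## Package layout

- `R/score_store.R` — TSV I/O, sparse bipartite table, per-entity views
- `R/o2a_baseline.R` — O2A curves, LOESS, Kneedle, median baselines
- `R/rp_features.R` — the 13 context features + raw score
- `R/cascade_model.R` — splits, negative sampling, gbm/rf cascade
- `R/evaluation.R` — bootstrap ROC/PR, Welch, DoS, λ-ranking, tiers
- `R/synthetic_data.R` — planted-structure generator
- `vignettes/reciprocal-perspective.Rmd` — methods notes and rationale
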
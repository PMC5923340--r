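# omistrat

Multi-omics stratification of severe septic shock patients by 28-day
mortality, built on the day-7 over day-1 (D7/D1) variation of targeted
metabolomics, iTRAQ proteomics and continuous clinical variables.

## Who this is for

Analysts working with small, deeply-phenotyped longitudinal cohorts —
tens of patients, hundreds of strongly correlated molecular features,
two time points — who want to identify the features whose *trajectory*
over the first week of treatment separates survivors (S) from
non-survivors (NS). The package is descriptive, not predictive: the
outcome of a run is a ranked, cross-model consensus of discriminative
features, not a prognostic score.

## What it computes

For each feature x measured at day 1 and day 7, the modeling substrate
is the per-patient ratio r = x(D7) / x(D1). The pipeline is:

* **QC** — metabolites kept iff missingness < 20% within every outcome
  group and ≥ 50% of concentrations above the limit of detection;
  proteins kept iff detected in all iTRAQ runs with ≥ 2 unique peptides
  and not a contaminant, then log2-transformed and LOESS-normalized
  against the per-protein mean intensity over all runs.
* **Univariate screen** — Wilcoxon rank-sum (between groups) and
  signed-rank (within groups, D1 vs D7) tests, exact for small untied
  samples, flagged only when p < 0.05 and Benjamini–Hochberg q < 0.15
  jointly.
* **Cascaded mRMR** — greedy minimum-redundancy maximum-relevance
  ranking on ternary-discretized ratios:
  step t picks argmax_f [ I(f; class) − mean_{s∈S} I(f; s) ]
  (MID criterion; MIQ quotient form available). Three tiers:
  metabolites; top-50 metabolites ∪ top-50 proteins, re-ranked; top-20
  of that pool ∪ 17 clinical variables, re-ranked.
* **Models** on the top-k ranked features (k = 10, 20, 30), Z-scored on
  the training patients of a stratified 2/3–1/3 split:
  * elastic-net logistic regression (glmnet, mixing weight α = 0.5,
    50 cross-validation repetitions) with two minimal-deviance
    strategies: A takes the coefficients at the (repetition, λ) pair of
    minimal CV deviance, B refits once at that λ;
  * LDA with Ledoit–Wolf-shrunk pooled covariance (top 10);
  * PLS-DA, 3 NIPALS components, class coded ±1 with *weighted
    centering* (each feature centered at the unweighted mean of its two
    class means, so the unbalanced majority class does not shift the
    boundary), VIP scores
    VIP_j = sqrt( p · Σ_a w²_ja SSY_a / Σ_a SSY_a ) (top 10 and 20).
* **Consensus** — features selected by every fitted model of a tier
  (nonzero coefficient, or VIP > 1).

A synthetic-cohort generator (`generate_cohort()`, preset
`septic_shock_cohort()`) provides study-shaped data with planted
ground-truth effects — block-correlated features, lognormal
concentrations, below-LOD censoring, per-group missingness, batch
structure — so the full pipeline is testable without patient data.

## Worked example

```r
library(omistrat)

cohort <- septic_shock_cohort(seed = 1)   # 9 S + 8 NS, 186 -> 137 metabolites
run <- run_pipeline(cohort, top_k = c(10, 20), seed = 1)
cat(pipeline_report(run), sep = "\n")
```

Output (abridged):

```
# Stratification run report

- Patients: 9 survivors (S), 8 non-survivors (NS); 28-day outcome rate 47%

## Feature funnel

- metabolite_qc: 186 in, 137 out
- metabolite_ratios: 137 in, 137 out
- protein_ratios: 132 in, 132 out
- clinical_ratios: 17 in, 17 out

## Significant features (p and FDR jointly)

- S_vs_NS_ratio: MAP, CVP, PROT_001, PROT_021, PROT_031, AC_30, AC_10, ...
- D1_vs_D7_within_S: none

## Top-ranked features per tier

- metabolites: AC_30, GPL_40, AC_20, AC_10, AC_35, GPL_84, GPL_08, ...
- all_layers: AC_30, MAP, PROT_011, AC_20, CVP, PROT_001, AC_10, ...

## Test-set performance

- metabolites / top10 / elastic_net: 6 and 6 of 6 test patients correct
- all_layers / top10 / lda: 6 of 6 test patients correct

## Consensus features (selected by all models)

- metabolites: AC_10, AC_20, AC_30, GPL_20
- all_layers: AC_10, AC_20, AC_30, CVP, MAP, PROT_001, PROT_011, PROT_021
```

Reading it: the cohort's 28-day outcome rate is 47% (8 of 17). The QC
funnel retains 137 of 186 panel metabolites. The joint p/FDR screen
flags the planted discriminative ratios (here acylcarnitine and
glycerophospholipid species, two proteins, and mean arterial/central
venous pressure among the clinical variables), the three mRMR tiers
place them at the top ranks, every model family classifies all 6
held-out patients at this seed, and the consensus rows list the
features selected by *all* models of a tier — the run's robust
signature. VIP scores from the integrated tier-3 PLS-DA confirm the
same features with VIP near or above 1:

```
PROT_021      CVP PROT_001    AC_30      MAP    AC_10    AC_20 PROT_011
    1.13     1.12     1.09     1.08     1.04     1.03     1.03     1.03
```

See `vignettes/omistrat-methods.Rmd` for the model assumptions, every
tunable parameter with its default and rationale, and known
limitations.

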
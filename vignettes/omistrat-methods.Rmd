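---
title: "Stratifying septic shock patients from longitudinal multi-omics ratios: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratifying septic shock patients from longitudinal multi-omics ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omistrat)
```

## The problem

Severe septic shock has highly heterogeneous outcomes: patients with
similar admission presentation diverge sharply over the first week of
treatment. `omistrat` implements an analysis strategy for small,
deeply-phenotyped cohorts measured at two time points — day 1 (acute
phase, D1) and day 7 (steady state, D7) after shock diagnosis — across
three layers: targeted plasma metabolomics (absolute concentrations,
µM), multiplexed iTRAQ plasma proteomics (normalized log2 peak
intensities), and continuous clinical variables. Patients are labelled
survivor (S, coded 0) or non-survivor (NS, coded 1) by 28-day
mortality.

The central modeling choice is to work on the per-patient **D7/D1
ratio** of each feature rather than on either time point alone: the
question is not who looks sickest at admission but whose molecular
trajectory over the first week diverges. The pipeline is descriptive,
not predictive — with 17 patients the goal is to identify the features
whose variation is most associated with outcome, with agreement across
several model families serving as the robustness check.

## Pipeline overview

1. **Quality control.** Metabolites are retained only if missingness
   (non-detectable peaks) stays below 20% within *each* outcome group
   (both time points pooled) and at least 50% of all their
   concentrations lie above the limit of detection (LOD). Proteins are
   retained only if detected in all iTRAQ runs, supported by at least
   two unique peptides, and not a depletion-target contaminant; raw
   intensities are log2 transformed and LOESS normalized against the
   per-protein mean intensity across all runs.
2. **Ratios.** D7/D1 per patient per feature; censored metabolite
   cells are imputed at LOD/2 first (see below).
3. **Univariate screen.** Wilcoxon rank-sum tests between groups (at
   D1, at D7, and on ratios) and signed-rank tests within groups (D1
   vs D7), with Benjamini–Hochberg control; a feature is flagged only
   when p < 0.05 **and** q < 0.15 jointly.
4. **Cascaded mRMR ranking.** Minimum-redundancy maximum-relevance
   ranking on the ratios in three tiers: metabolites alone; the top 50
   metabolites pooled with the top 50 proteins, re-ranked; the top 20
   of that pool plus all 17 clinical variables, re-ranked.
5. **Models.** On the top-k ranked features (k = 10, 20, 30), Z-scored
   on the training patients: elastic-net logistic regression with two
   minimal-deviance selection strategies; LDA on the top 10; PLS-DA
   with 3 components and weighted centering on the top 10 and 20, with
   variable importance in projection (VIP) scores.
6. **Consensus.** Features selected by every fitted model of a tier
   (nonzero coefficient, or VIP > 1) are reported as the tier's robust
   signature.

## Statistical machinery and parameter choices

### QC thresholds

The missingness rule is evaluated **per group with both time points
pooled**: the retention decision must not be driven by one group's
assay failures, and pooling time points keeps the rule stable at n = 9
and 8 per group. Both thresholds (`max_missing_frac = 0.20`, strict;
`min_above_lod_frac = 0.50`, inclusive) are arguments of
`filter_metabolites()`. The rules are order-independent and every
excluded feature carries all the rule codes it violated.

### LOESS normalization of iTRAQ intensities

Each sample's log2 intensities are compared with a reference — the
per-protein mean across all samples of all runs — and a degree-1 LOESS
curve of the deviation versus the reference is subtracted
(`span = 0.75`; neither value is critical, they are the conventional
MA-normalization defaults). The reference could also be read as one
global scalar; that variant (`reference = "global_scalar"`) degenerates
to per-sample centering and is kept as a flag. We default to the
per-protein mean because a scalar reference cannot remove an
intensity-*dependent* bias, which is the point of LOESS normalization.

### Censoring and missingness before ratios

A below-LOD concentration is known to be small, so it is imputed at
LOD/2, the standard targeted-metabolomics convention; the alternative
(`lod_impute = "drop"`) drops affected features instead. A cell missing
completely at random carries no value information, so it is imputed at
the per-feature, per-time-point median — imputing MCAR cells at LOD/2
would systematically fabricate extreme ratios whenever a denominator is
affected. Features still lacking a usable denominator are dropped with
reason `zero_denominator`. Ratios, not log-ratios, are the modeling
features; the generator does its effect bookkeeping on the log2 scale
where shifts are additive.

### Rank tests

Rank-sum and signed-rank p-values are exact (full enumeration of the
null distribution) for up to 25 untied observations, and use the
normal approximation with midranks, tie correction and continuity
correction otherwise. Zero differences are dropped before signed
ranking — stated explicitly because at n = 8 or 9 the convention is
visible in the result. The within-group trend (up/down/flat) is called
from the median of all differences, zeros included. The package treats
the paired D1-vs-D7 comparison with the signed-rank test because the
data are paired; rank-sum between groups, signed-rank within. FDR is
controlled per comparison family per layer (`fdr_scope = "family"`),
with a global option; the dual p-and-q rule is what the screening
stage flags.

### mRMR: discretization, criterion, tie-breaking

Features are ternary-coded at mean ± ασ before mutual information is
estimated (plug-in, base 2). The default multiplier is **α = 0.5**.
This is a deliberate design decision with a derivation behind it: for
a feature separating two balanced classes by a shift D with
within-class spread s, the class means sit
(D/2)/√(s² + D²/4) pooled standard deviations from the overall
mean — a quantity strictly below 1 for every D. Coding at one full
sigma therefore leaves *both* class modes inside the middle band no
matter how strong the effect, and the resulting codes are nearly blind
to group structure; at half a sigma the coding resolves shifts larger
than about 1.15 within-class standard deviations. The MID (difference)
criterion is the default, with MIQ (quotient) available. Ties — which
are common with 17 samples and ternary codes — are broken by higher
relevance, then input column order, and scores within a relative 1e-9
band are treated as tied so the ranking cannot depend on
floating-point summation order. Because discretization is
location-scale equivariant, ranking on raw versus Z-scored ratios is
immaterial; the package ranks raw ratios, before the split, and the
tier-2 cascade reuses the tier-1 ranking for its metabolite cut rather
than recomputing it.

### Elastic net

Penalized logistic regression with mixing weight α = 0.5 — an even
compromise between lasso's selection and ridge's grouping of
correlated features, which matters here because lipid species of one
class are strongly correlated. The λ grid has 100 geometric values
from λ_max (the smallest λ zeroing all slopes) down to 10⁻⁴ λ_max.
What varies across the 50 repetitions is the cross-validation fold
assignment on the *fixed* training set (5 stratified folds, capped at
the smallest training class size): the train/test split itself is
fixed. Strategy A returns the coefficients of the model with the
minimal cross-validated binomial deviance over all (repetition, λ)
pairs; strategy B takes that λ and refits once on the full training
set. Classes are called at 0.5 on the logistic output. Note that
minimizing deviance across repetitions has a winner's-curse flavour:
on separable training data it systematically favours the smallest λ
of the grid, so the selected models are nearly unpenalized — a
property of the selection rule itself, reported here because users
should not expect strategy A to produce sparse models on separable
data.

### LDA

The pooled within-class covariance is shrunk towards a scaled
identity. The shrinkage intensity defaults to the Ledoit–Wolf
estimate (`shrinkage = "auto"`), the standard automatic choice when
the feature count (10) approaches the number of training patients
(11); on such data the estimate is typically 0.7–1.0, i.e. close to
diagonal LDA, which is what the bias-variance trade-off demands there.
A fixed γ is accepted, and γ = 0 recovers plain LDA with an explicit
error on singular covariances. Priors are equal by default, so in one
dimension the boundary sits at the midpoint of the class means.

### PLS-DA, weighted centering and VIP

The class is coded S = −1, NS = +1 and components are extracted by
NIPALS. Because the groups are unbalanced (9 vs 8), each feature is
centered at the unweighted mean of its two class means (**weighted
centering**), so both classes pull the origin equally and the decision
boundary — the sign of the predicted response — is not dragged toward
the majority class. With balanced classes this coincides with ordinary
centering exactly. Three components are used (bounded by
min(n_train − 1, k), enforced with an explicit error). VIP scores are

VIP_j = sqrt( p · Σ_a w²_ja SSY_a / Σ_a SSY_a ),

with w_a the unit-norm weight vectors and SSY_a the response variance
explained by component a; since Σ_j w²_ja = 1 the mean squared VIP is
identically 1, an algebraic identity the test suite verifies
numerically on random fits. The conventional selection cut is VIP > 1.

### Split and Z-scoring

The 2/3–1/3 split is stratified per class with half-up rounding, so 9
S + 8 NS gives 6 + 5 training and 3 + 3 test patients. Z-scoring is
fitted on training rows only and applied to the test rows — the
leakage-free default — with `scope = "all"` reproducing the
normalize-everything-first behaviour for compatibility.

## The synthetic cohort generator

No patient-level data ship with the package; every stage is exercised
on synthetic cohorts with planted truth. `generate_cohort()` draws D1
levels per layer (lognormal µM concentrations with log-means uniform
over a plausible range; Gaussian log2 intensities around 12–18 with
per-run batch offsets; clinical variables on their natural scales,
truncated to physiological bounds), then sets
D7 = D1 · 2^(shift + noise), where the shift differs between outcome
groups only for planted features. Features come in blocks sharing a
latent Gaussian factor (default ρ = 0.5, block size 5) both at
baseline and in the ratio noise, emulating the strong co-variation of
lipid species that motivates the elastic-net and redundancy machinery.
Metabolite values below their per-feature `lod_quantile` quantile
(default 0.05) are flagged censored — not deleted — and per-group
missingness (default 0.02) is applied completely at random to the
metabolite layer.

`septic_shock_cohort()` is the study-shaped preset: 9 S + 8 NS
patients, a 186-analyte panel (40 amino acids and biogenic amines, 40
acylcarnitines, 90 glycerophospholipids, 15 sphingomyelins, 1 hexose)
of which exactly 137 pass QC by construction (25 features violate the
missingness rule, 24 the LOD rule), 132 proteins in 6 iTRAQ runs, the
17 continuous clinical variables, and about ten planted effects split
across layers (6 metabolites, 4 proteins, 2 clinical), each a 3σ shift
(|shift| = 0.75 on the log2 scale against ratio noise of SD 0.25),
mostly downward in non-survivors — the direction reported for
phosphatidylcholine species in this setting. The published study gives
no effect-size estimates beyond box plots, so the 3σ magnitude is a
free parameter chosen to represent a clearly-resolvable biological
effect, not a calibration to any published figure.

What the generator does **not** emulate: mass spectra and
peptide-level evidence (beyond a unique-peptide count), real
inter-metabolite biochemistry, informative (value-dependent)
missingness, and organ-failure composite scores. Passing tests
therefore demonstrate that the machinery recovers structure it is
pointed at under realistic noise, censoring and correlation — not that
any particular biological claim generalizes.

## Numerical conventions

* Quartiles by linear interpolation (`quantile` type 7); integer
  percents rounded half-up (62.5% → 63%).
* Standard deviations with denominator n − 1 throughout.
* Zero-variance features are dropped from Z-scoring with a warning and
  recorded.
* mRMR ties: relative 1e-9 score band, then relevance, then column
  order; identical seeds give bit-identical runs end to end.
* Exact rank tests switch to the normal approximation exactly when
  ties appear or the sample exceeds 25 observations.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script experiments use 20 study-shaped
cohorts (17 patients each) for the recovery checks, 1000 null features
at the study's group sizes for the joint-screen calibration, and
10,000 null features at 30 + 30 patients for the p-value uniformity
check — sizes chosen so each check has enough resolution to fail
informatively while the whole suite runs in minutes on a laptop.

## Known limitations

* **Half-LOD imputation creates heavy-tailed ratios.** The true
  D7/D1 ratio of a generated feature is tail-free by construction, but
  imputing a censored denominator at LOD/2 inflates that patient's
  ratio by up to 2× (about +4 noise SDs; deflation when the numerator
  is censored). With 11 training patients, mRMR-selected
  chance-separating null features give such cells real leverage: in
  the shipped 20-seed experiment every model family classifies the
  whole 6-patient test set in 14 of 20 seeds (mean test accuracy
  98.3%), with the misses concentrated in the metabolites-only tier
  and traceable to exactly this mechanism. The imputation convention
  and the censoring level are both kept as-is — the first is the
  field's standard, the second a realism choice — so users of the
  preset should expect occasional single-patient misses in the
  smallest tier rather than uniform perfection.
* The minimal-deviance-across-repetitions rule favours near-zero λ on
  separable training data (see above); the two strategies then nearly
  coincide.
* mRMR with the MID criterion penalizes planted features for sharing
  the class signal: with several strong true effects, the tail of the
  true set can rank below redundancy-free noise. This is inherent to
  the criterion, not a defect of the implementation (which matches an
  exhaustive oracle exactly).
* With 17 patients nothing here is a prediction model; test-set
  correct-classification counts on 6 patients are a sanity check, not
  a performance estimate.
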
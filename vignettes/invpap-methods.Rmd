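---
title: "Methods: proteomic biomarker discovery for inverted urothelial papilloma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteomic biomarker discovery for inverted urothelial papilloma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invpap)
```

# The problem

Inverted urothelial papilloma (IUP) is a rare, benign-behaving bladder
neoplasm whose endophytic growth pattern closely mimics papillary urothelial
carcinoma (PUC) with inverted growth; the two are a well-known diagnostic
pitfall. `invpap` implements, as a reusable and tested pipeline, a
label-free proteomic workflow for discovering immunohistochemistry-ready
biomarkers that separate the two entities: differential expression with
permutation-based FDR control on an iBAQ-style abundance matrix (9 IUP / 12
PUC / 10 normal urothelium in the motivating design), partitioning of the
IUP proteome into low-risk ("NU-like") and high-risk ("PUC-like")
signatures, SVM-based feature selection, a public-atlas concordance screen,
H-score/ROC validation in an independent 25-vs-16 immunohistochemistry
cohort, and univariate survival screening in a 405-patient expression
cohort.

Every stage is exercised on synthetic data whose generators plant known
structure, so the package's guarantees are stated as *recovery* properties
(does the pipeline find what was planted?) rather than as reproductions of
any particular cohort's numbers.

# Preprocessing model

The abundance matrix holds raw iBAQ-scale intensities with `NA` for
non-detection. Preprocessing follows the standard label-free chain:

* **Presence filter.** A protein is kept when detected in at least a
  fraction `min_presence_fraction` (default 0.20) of samples. The
  comparison is inclusive on the exact fraction — 2 detections in 10
  samples survives a 0.20 threshold, 6 in 31 (0.194) does not — with no
  rounding of counts.
* **Log2 + median centring.** Intensities are log2-transformed and each
  sample column is shifted so its median of present values is zero.
  Median centring is the default because it is robust to the asymmetric
  missingness of label-free data; `"none"` is available when intensities
  arrive pre-normalized.
* **Downshifted-normal imputation.** Missing values are drawn per sample
  column from `N(mean - 1.8*SD, (0.3*SD)^2)`, the convention for
  left-censored proteomics data in which low-abundance proteins drop out
  preferentially. Width 0.3 and downshift 1.8 are the widely used defaults
  of desktop proteomics software; both are configurable, and `"none"`
  switches the statistics to present-value testing (requiring at least two
  present values per group). Imputation never alters present values and is
  reproducible under the configured seed.

# Permutation statistics

The differential-expression engine computes a Welch-style two-sample
statistic (optionally moderated by an additive fudge constant `s0` in the
denominator, default 0) or a one-way F statistic, and obtains inference by
permuting sample labels with group sizes preserved. The same permutation
set is reused across all proteins in a round (row-wise exchangeability, the
SAM convention), which preserves the correlation structure across proteins.

* **p-values** use the add-one rule `p = (1 + #{permuted |stat| >=
  observed |stat|}) / (1 + B)`, so no p-value is ever zero and the floor is
  `1/(B+1)`. For tiny groups the permutation distribution is coarse: with
  3-vs-3 samples only 20 label assignments exist and the smallest
  attainable two-sided p is 0.1, which the sampler converges to (this is a
  property of permutation inference, not a resolution limit of the
  implementation).
* **q-values** follow the permutation-FDR construction: at each observed
  |statistic| threshold, the expected number of false positives is the
  *average* across permutations of the matrix-wide count of permuted
  statistics exceeding the threshold; dividing by the observed count and
  enforcing monotonicity gives the q-value. The average is used rather
  than the median of counts deliberately: at the extreme tail the count
  distribution is concentrated on {0, 1}, so the median is 0 in roughly
  half of null datasets and would hand the top-ranked protein a spurious
  q of 0. With averaged counts the realized false-discovery proportion on
  global-null matrices (31 samples, 500 proteins, 1,000 permutations) is
  essentially 0 at the 0.05 level, which the acceptance suite verifies
  over 20 seeds.

Defaults: 1,000 permutations, FDR level 0.05, `s0 = 0`.

# Signature partition

A protein significant in the three-group ANOVA is classified by the
similarity pattern of IUP against the two reference tissues, assessed with
post-hoc two-group permutation t-tests at the same FDR level:

* `NU_like_*`: IUP indistinguishable from normal urothelium but different
  from carcinoma (low-risk signature);
* `PUC_like_*`: the reverse (high-risk signature);
* `up`/`down`: the sign of `mean(IUP) - mean(dissimilar group)`;
* anything else stays `unassigned` — the partition is deliberately
  conservative and never forces a nearest-pattern assignment.

The post-hoc tests are computed genome-wide and then restricted to the
ANOVA-significant proteins. Running the FDR machinery inside the enriched
significant subset instead would calibrate the null side of the pattern
rule against a distribution dominated by true effects, and in simulation
this misassigned several percent of planted proteins; the genome-wide
variant matches how pairwise t-tests are ordinarily reported alongside an
ANOVA and recovers 93–96% of planted classes at the study's group sizes
(effect 2.0 log2 units, residual SD 0.5, 20% MNAR dropout), counting
proteins erased entirely by dropout as failures.

Per-class rankings order proteins by ascending ANOVA q, breaking ties by
descending |F| and then protein id, and truncate to the top 40 by default.

# SVM-RFE feature selection

Feature selection is recursive elimination around an RBF-kernel
support-vector classifier. The RBF kernel has no primal weight vector, so
each feature is scored by the change in the kernel-space margin objective
`W2 = sum a_i a_j y_i y_j K(x_i, x_j)` when the feature is divided out of
the kernel (the standard nonlinear RFE criterion); the lowest-scoring 10%
of remaining features (at least one) leave each round. Stratified
cross-validated error (default 5-fold, folds fixed per seed, features
standardized inside each training fold only) is recorded at every panel
size the schedule visits, and the chosen panel is the smallest size
achieving the minimum error.

Two numerical choices matter on cohorts of a few dozen samples:

* **Kernel width.** With standardized features, squared sample distances
  concentrate near `2 * n_features`, and the conventional `gamma = 1 /
  n_features` puts the kernel deep in its nonlinear regime, where the
  margin-objective score loses contrast between informative and noise
  features — in simulation, chance discriminators then outrank planted
  3-SD features. The default is `gamma = 0.1 / n_features`, a mildly
  nonlinear regime in which planted separating features rank in the top
  three in every tested fixture; any scale in 0.05–0.25 behaves
  equivalently.
* **Cost.** Default `cost = 10`: a firmer margin than the textbook 1,
  which stabilizes the ranking when classes are separable.

Shortlisting reorders the chosen panel by the unweighted sum of each
protein's machine-learning rank and its rank by ascending t-test q-value,
and keeps the top 5 — the rule that reduced a 10-protein panel to five
candidates in the motivating workflow. On strongly separable synthetic
data a single protein often achieves zero cross-validated error, in which
case the chosen panel (and hence the shortlist) legitimately collapses to
one protein and a warning notes that `k` exceeded the panel.

# Atlas concordance screen

The immunoscore of an antibody staining profile is `4*p_high + 3*p_medium
+ 2*p_low + 1*p_not_detected`, averaged over antibodies — a convex
combination of {1, 2, 3, 4}. A candidate is excluded when the atlas calls
it relatively overexpressed in urothelial carcinoma (immunoscore at or
above a cutoff, default 2.5 — the scale midpoint, since no threshold is
standard) while the proteomics found it higher in IUP (positive log2 fold
change, i.e. down in carcinoma). Candidates without a score or fold change
are flagged unscreenable and retained, so missing atlas coverage never
silently removes a biomarker. Profiles are consumed from a local TSV
snapshot; the package performs no network access.

# IHC validation statistics

* **H-score** per specimen: `1*(% cells 1+) + 2*(% cells 2+) + 3*(% cells
  3+)` with all detected cells, 0-intensity included, in the denominator;
  range 0–300.
* **Group comparison**: Mann–Whitney, exact when the smaller group has at
  most 8 observations and no ties, otherwise the tie-corrected normal
  approximation with continuity correction.
* **AUROC**: the normalized Mann–Whitney U (tied pairs count 1/2), with
  the Hanley–McNeil standard error at the observed AUC and a two-sided
  test against 0.5; under perfect separation the observed-AUC SE is zero
  and the null-AUC SE is substituted. A DeLong variance is available as an
  option.
* **Youden cutoff**: thresholds are placed at midpoints between adjacent
  distinct scores; the threshold maximizing sensitivity + specificity − 1
  is returned, ties resolving to the lowest threshold. The direction flag
  (positives score higher, by default) is exposed because published
  cutoffs do not always state their orientation.
* **Confidence intervals**: Clopper–Pearson exact intervals from beta
  quantiles, returned in percent and rounded only at presentation. The
  standard clinical checks — 18/25 giving (50.6, 87.9) and 16/16 giving
  (79.4, 100) at 95% — are asserted in the test suite.

# Survival screening

Univariate Cox proportional-hazards regression on continuous log2
expression uses Efron tie handling (the modern default; the upstream
choice is rarely stated) and reports the per-doubling hazard ratio with a
95% Wald interval. The Kaplan–Meier view splits the cohort at the median
expression — ties go to the low group, documented because expression
medians tie frequently on real data — and compares arms with the 1-df
log-rank test. Both are backed by the `survival` package; the classical
identity between the Cox score test and the log-rank statistic for a
binary covariate is used as a cross-check in the tests.

# Synthetic-data generators

The generators produce every input the pipeline reads, with ground truth
recorded for recovery testing:

* **Abundance**: per-protein log2 baselines `N(25, 2)` (an iBAQ-like
  dynamic range), planted signature classes shifted by `effect_size`
  (default 2.0 log2 units, 40 proteins per class) in their class's
  pattern, residual noise SD 0.5, and *MNAR* dropout — values below each
  sample's 20% detection-limit quantile go missing — rather than uniform
  missingness, so the imputation path is exercised the way label-free
  data actually stresses it. Cohort shape defaults to 9 IUP / 12 PUC / 10
  NU samples and 5,000 proteins.
* **IHC**: per-specimen multinomial draws over intensity bins 0–3;
  defaults emulate a 25 IUP / 16 PUC validation cohort stained for a
  papilloma-retained marker (expected H-scores 95 vs 10, from the closed
  form `100*(p1 + 2 p2 + 3 p3)`).
* **Survival**: 405 patients, standard-normal expression, exponential
  event times with hazard `0.02 * exp(beta * x)` per month and a default
  per-doubling log hazard ratio of 0.25 (the magnitude class of
  prognostic signature proteins); uniform censoring calibrated on the
  drawn event times to hit the target censoring fraction (default 50%)
  approximately.
* **Staining profiles**: concordant (low-intensity atlas profile) or
  discordant (high-intensity profile with positive planted IUP-vs-PUC
  fold change) regimes for screen testing.

What the generators do *not* emulate: correlated protein co-expression
blocks, batch effects, heavy-tailed intensity noise, specimen-level
staining heterogeneity beyond multinomial sampling, and non-proportional
hazards. Passing recovery tests therefore demonstrate that the machinery
is correct under the stated model, not that any particular real cohort's
headline numbers (protein counts, DEP totals, signature sizes, error
rates, AUROC, hazard ratios) are reproducible — those depend on data the
package does not consume.

# Problem sizes in the shipped tests

The test suite scales simulations to what the properties need rather than
to the full 5,000-protein matrix: FDR calibration uses 20 global-null
matrices of 500 proteins with 1,000 permutations; signature recovery uses
1,000-protein matrices over 3 seeds (1,000 permutations); feature-selection
recovery uses 50-feature, 21-sample fixtures over 10 seeds; Youden/AUC
oracle equivalence uses 100 random small instances; Cox recovery uses 20
cohorts of 405 patients. The acceptance script runs one seed of each at
the same sizes.

# Known limitations

* The permutation engine reuses one permutation set across proteins per
  round; per-protein missingness patterns are handled by present-value
  statistics rather than per-protein permutation sets.
* The SAM-style FDR is a plug-in estimator without a pi0 correction, so
  q-values are mildly conservative when many proteins are truly
  differential.
* RBF-kernel RFE scores features against the current model fit; like all
  greedy elimination schemes it offers no optimality guarantee for
  correlated panels (duplicated features are ranked adjacently, which the
  tests assert, but highly collinear blocks may share credit
  arbitrarily).
* The IHC generator draws cells independently within a specimen, so
  between-specimen H-score spread shrinks as cells-per-specimen grows;
  AUROC on default settings is accordingly near 1.
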
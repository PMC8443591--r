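---
title: "Methods: multi-block integration of exposure, metabolome, microbiome and clinical signs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-block integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skinomics)
```

This vignette is the package's account of its statistical machinery: the
models and their assumptions, the tunable parameters and their defaults,
what the synthetic cohort generator does and does not emulate, and the
numerical choices made where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The design being analyzed

The package targets a two-city observational design: 67 women per city, one
city markedly more polluted; per subject, a hair PAH panel (39 analytes, a
chronic-exposure biomarker), a stratum-corneum metabolite table (~350
features with super-/sub-pathway labels), bacterial and fungal OTU relative
abundances from cheek swabs (~143 taxa), and dermatologist-scored facial
signs (ordinal 1–4 severities and binary presences). All p-values from such
a design are exploratory: the study is observational and associations may
be confounded — the city term being the obvious one, which is why the
cross-block analyses support group-mean-centering adjustment.

## Clinical statistics

**PAH score.** The 39 PAH concentrations span orders of magnitude, so the
exposure summary is the first principal component of the log-transformed,
centered and *scaled* panel (correlation PCA). The component sign is fixed
by positive correlation with the mean log concentration, so a larger score
always means more exposure. Subjects are split at the score median; ties at
the median go to the "below" group (a convention — at 134 distinct scores
the median is unique and the split is 67/67). Concentrations at or below
the detection limit must be handled by the caller; `lod_impute` imputes
LOD/2 before the log, a common census convention.

**Ordinal signs.** Severity scores tabulated 2 × k are compared with a
rank-sum test in the convention of classical clinical reporting software:
midranks within tied categories, tie-corrected variance
n₁n₂/12 · [(N+1) − Σ(t³−t)/(N(N−1))], a 0.5 continuity correction on the
rank sum, and a two-sided p referred to Student's t with N−1 degrees of
freedom. The plain normal reference is available (`wilcoxon_normal`), but
the t reference is the default because it is what the published table used
(the test suite verifies all printed p-values to four decimals from
reconstructed counts). At small N the approximation deviates from exact
enumeration by up to ~0.15 in p (tested); at the design's N = 134 it
tracks the permutation distribution to ~0.01.

**Binary signs.** Pearson chi-squared without the Yates correction, 1 df —
again the convention that reproduces the published values exactly.
Prevalence is 100 × (1 − n_No/n), reported to one decimal with
half-away-from-zero rounding, the same rounding used to reconstruct counts
from printed percentages (`round(pct × 67/100)`; every reconstructed group
sums to 67, which validates the rounding choice).

## Differential metabolome

Fold changes are ratios of group means on the original abundance scale,
computed after removing *extreme* outliers: values at or beyond
Q3 + 3·IQR or Q1 − 3·IQR within each group. The fence is anchored at the
quartiles and two-sided; with IQR = 0 or fewer than 4 values the data pass
through unchanged (any other rule degenerates). Outlier trimming applies to
the fold change **only**: the Welch t-test runs on the log values of all
subjects, because trimming tails before a t-test shrinks its variance
estimate and demonstrably inflates the false-positive rate under a global
null (the acceptance suite measures the null selection rate). Whether the
original analysis pooled variances is not documented; Welch is the safer
default and at n = 67 per group the difference is negligible.

Benjamini–Hochberg q-values are computed across all features of the block;
a feature is called significant when |log2FC| > 0.6 **and** q < 0.05, both
strict, matching the published threshold semantics (a feature at exactly
0.6 is not called). Positive log2FC means higher abundance in the
non-reference group (second factor level — the more polluted city in the
intended orientation); the test suite pins the sign convention by a
label-swap antisymmetry property. The same machinery serves targeted
protein panels (ratio + t-test); no separate code path exists.

Pathway display is aggregation, not enrichment: mean log2FC per sub-pathway
with per-feature −log10(q) stars. An optional two-sided hypergeometric
over/under-representation test is provided but off by default, since the
pathway labels are input metadata, not an ontology.

## Random forest and permutation importance

City membership is modelled with a standard bootstrap tree ensemble
(`randomForest`; n_trees defaults to 1000, mtry to √p). The out-of-bag
bookkeeping is deliberately owned by this package: each subject's OOB
prediction is the majority vote over trees whose bootstrap excluded it
(ties break to the earlier class level), so the identical vote can be
replayed with one feature's values permuted. VIMP is the difference of OOB
error rates (permuted − observed), on the error-rate scale, with a single
global permutation per feature: cheaper than per-tree permutation and the
same estimand; a feature no tree uses gets exactly zero. The reference
implementation's per-tree scheme averages over more permutation noise but
does not change what is being estimated.

## Sparse canonical correlation

The two-block associations (PAH ↔ metabolites; bacterial or fungal OTUs ↔
metabolites, city-adjusted) use rank-1 sparse CCA via penalized matrix
decomposition on column-standardized blocks: alternating updates
u ← normalize(soft(X′Yv, δ)) with δ chosen so ‖u‖₁ ≤ c₁ (δ = 0 when the
bound is slack), and symmetrically for v. The soft-threshold δ is solved in
closed form on the sorted-|a| segment whose L1 range brackets the bound (a
quadratic per segment), which the tests verify against a bisection oracle
to ~1e-12; the objective is asserted nondecreasing at every sweep, and with
slack bounds the fit matches the leading singular pair of X′Y.

Sparsity is parameterized as a fraction f with c = f·√p over the default
grid f ∈ {0.1, …, 0.7}. Tuning permutes the rows of X only (the standard
two-block scheme; permuting both blocks identically would leave the
correlation invariant, which the tests check), Fisher-transforms the
canonical correlations, and scores each grid point by
(z_obs − mean(z_perm)) / (sd(z_perm) + 0.05). The 0.05 stabilizer matters:
at the sparsest grid points the permutation distribution of the best
single-pair correlation is extreme-value compressed, and without the
stabilizer the criterion degenerates toward always selecting a single
feature pair.

**Significance under selection.** Because the reported grid point is
chosen by maximizing the score, the naive tail fraction of permuted z at
that point is anti-conservative — measured at a ~0.12–0.15 rejection rate
at nominal 0.05 under independent blocks. The primary `p_value` therefore
compares the observed maximal score against the permutation distribution
of the grid-maximal score (a maxT correction using the same permutations),
which restores calibration (the acceptance suite measures ~0.05 over 200
null runs). The uncorrected at-chosen-point fraction is still reported as
`p_value_chosen` for comparability with the classical tuner. Both use the
add-one convention, so the smallest attainable p is 1/(nperms+1) — with
the study's nperms = 500 that is ~0.002.

## Diversity links

The Shannon index is the plug-in entropy of observed proportions. This
deliberately replaces richness-modelling estimators: the downstream
operations accept any externally supplied diversity vector, so users with a
preferred estimator can inject it. Metabolite–diversity screening is plain
Pearson correlation with t-based p-values and BH control. "Variance of
diversity accounted for by the metabolome" is computed by PLS1 (NIPALS) on
autoscaled predictors, reporting both the in-sample cumulative R²Y and a
7-fold cross-validated Q² (the convention of the chemometrics software
named in the original analysis); which of the two the original figures
reported is not documented, so both are exposed. In-sample R²Y recovers a
planted explained variance within ±0.1 at n = 134 but carries the usual
optimism at large p; Q² is the conservative counterpart and goes negative
on pure noise.

## Consensus space and clustering

MAXVAR-A is realized as superblock RGCCA: each block connects only to the
superblock (the column concatenation of all standardized blocks), block
shrinkage τ = 1 (weight-norm constraint), superblock τ = 0 (unit component
variance), squared-covariance (factorial) scheme. This is a recognized
equivalence; an implementer preferring the original parameterization can
substitute it — the degeneracy tests (single block ⇒ PC1; duplicated
blocks ⇒ shared PC1; three blocks sharing one factor ⇒ consensus
correlates > 0.9 with it) pin the intended behavior. The superblock
covariance is singular whenever features outnumber subjects, so its
inverse is ridge-stabilized (fraction 1e-8 of the mean diagonal). The
criterion is asserted monotone at every iteration. Component 2 deflates
every block, and the superblock, against its *own* component-1 scores, so
within-block score vectors are orthogonal. Blocks exhausted by deflation
(e.g. a single selected feature) receive zero weights thereafter.

Variance explained per component is the mean squared correlation of the
original superblock columns with the component. Clustering is Ward (D2) on
Euclidean distances over the two consensus components, both components
equally weighted (the consensus scores are unit-variance by construction,
which settles the open weighting question in favor of equal weights). When
k is not fixed, it is chosen by the dendrogram gap: the k in [2, 10]
maximizing the drop between consecutive merge heights — the formalization
of "look at the largest gap in the tree".

By default the consensus runs on the sCCA-selected features of each block
(union over the two metabolite supports), as in the original workflow; a
flag switches to full blocks.

## v-tests

For a continuous variable, v = (x̄_k − x̄) / √((s²/n_k)·(N−n_k)/(N−1)) with
s² the global divide-by-N variance — the exact formula of the classical
cluster-characterization routine, matched so that published v-values are
comparable. For a categorical modality, the count of carriers inside the
cluster is referred to the hypergeometric law (draw n_k of N with n_j
carriers), the two-sided p is twice the smaller tail capped at 1, and
v = sign(p̂_k − p̂)·Φ⁻¹(1 − p/2); p = 1 maps to v = 0. |v| ≥ 2 flags a
characterizing variable, with no multiplicity correction (the flag is
descriptive, and the null flag rate is by construction the two-sided
normal tail ≈ 4.6%, which the acceptance suite verifies). Continuous
blocks are tested on the log scale by default, where abundances are
roughly symmetric; raw-scale testing is a flag.

## The synthetic cohort generator

`generate_cohort()` emulates the design's *structure*, not its biology.
All blocks derive from a latent Gaussian factor model on the log scale;
metabolites and PAHs are exponentiated (log-normal), OTU intensities are
closed to relative abundances (compositional; optional zero-inflation).
Planted, and recorded in `truth`:

* two sparse canonical pairs — a factor loading only on
  `sparse_support_size` features of the metabolite block and of the PAH
  (respectively OTU) block, with latent-projection correlation
  `canonical_correlation` (default 0.7);
* four clusters whose centers tilt the two canonical factors (clusters
  *are* cross-block structure — this is what makes the sCCA → consensus →
  Ward pipeline able to recover them) and additionally shift a disjoint
  marker subset per block;
* a city mean shift on all log-PAH features (default 1 SD);
* one ordinal and one binary clinical sign from thresholding a
  cluster-tied Gaussian latent at fixed quantiles (0.60/0.85/0.95 and
  0.75), reproducing sparse upper severity categories.

Defaults and why: `noise_sd = 1` makes the within-support feature
correlation 0.5, planting *diffuse* multi-feature covariation — with much
less feature noise a single feature pair carries nearly the whole
canonical correlation and any permutation tuner rightly collapses to a
support of one, unlike the multi-feature supports the workflow is meant to
select. `cluster_separation = 5` (within-cluster SD units between adjacent
centers) encodes clearly separated consensus clusters, the regime in which
a dendrogram-gap rule is the appropriate instrument; with separation 0 the
clusters are pure labels and downstream recovery is at chance, which the
tests use as a negative control. At `cluster_separation > 0` the shared
cluster geometry adds cross-block covariation on top of
`canonical_correlation`; the correlation knob is therefore verified in
isolation (separation and city effect zero), where the planted-projection
correlation equals the requested value.

What the generator does **not** emulate: no city effect in the metabolite
or OTU blocks (so volcano and random-forest stages see an honest null on
default synthetic cohorts — passing pipeline tests say nothing about
recovering the real study's metabolite–city contrasts), no compositional
zero-inflation by default, no feature-feature correlation beyond the
planted factors, no batch or subject-level covariates. Published
multivariate outcomes (canonical correlations 0.539/0.618/0.436, 45.9%
consensus variance, cluster compositions, importance rankings, 35%/14%
PLS figures) depend on the undeposited cohort data and are treated as
reporting-format references only — nothing in the tests aims at those
numbers.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: zero-variance columns are
dropped (with warnings) before standardization; constant scores make the
median split warn and assign everyone "below"; IQR = 0 disables outlier
trimming; a zero permutation spread warns and is stabilized by the +0.05
term; hierarchical clustering of two points returns two singletons.
Convergence tolerances are relative (1e-8 for PMD, 1e-10 for the consensus
criterion) with iteration caps and non-convergence flags rather than
errors.

The test and acceptance runs use deliberately scaled problem sizes chosen
to keep the full suite in the minutes range on a single core while leaving
each property's signal-to-noise ample: 200 null tuning runs at nperms =
100 and 100 subjects; 20 cohorts of 134 subjects for end-to-end cluster
recovery (nperms = 30, 100 trees); 20 seeds for each calibration property.
The study-scale settings (nperms = 500, 1000 trees) remain the function
defaults.

## Known limitations

The Wilcoxon t-approximation is a large-sample device; exact enumeration
is preferable below ~20 subjects. The sparse CCA is rank-1 by design
(first components only); multi-component deflation is out of scope. The
v-test battery is uncorrected for multiplicity, as in the original
workflow. The maxT-corrected permutation p-value reuses the tuning
permutations; with very small nperms its resolution is coarse
(1/(nperms+1)). The consensus realization fixes one of several MAXVAR
normalizations; weights are comparable within a fit, not across
parameterizations.
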
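---
title: "Brain-age modelling from multimodal connectivity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain-age modelling from multimodal connectivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connage)
```

## The analysis in one paragraph

`connage` implements an analysis chain common in ageing neuroimaging: derived
per-subject matrices (regional resting-state time series, streamline-count
structural connectivity, node volumes, tissue densities) are turned into a
multimodal feature vector; a cross-validated Lasso predicts chronological age
from those features; the residual — predicted minus chronological age, the
*brain-age gap* — is treated as a marker of accelerated or decelerated brain
ageing and related to graph-theoretic network properties, psychological
resilience, cognitive screening scores and emotional measures through
covariate-adjusted correlations, canonical correlation analysis and
clustering. Because cohorts of this kind are rarely shareable, the package
ships a synthetic cohort generator that plants the statistical structure the
analysis is meant to detect, so every stage can be tested end to end.

## Connectivity features

**Static functional connectivity** is the Pearson correlation matrix of the
regional time series (`static_fc()`).

**Dynamic connectivity** uses a rectangular sliding window (`window_spec()`,
default length 50 timepoints). The default step is 2: with 265 retained
volumes this yields `floor((265 - 50) / 2) + 1 = 108` windows. A step of 1
(which would give 216 windows on the same series) is equally supported; the
step is a configuration knob rather than a constant because both conventions
appear in the sliding-window literature. No tapering is
applied; none is conventional for plain sliding-window correlation.

**Nodal temporal variability** summarizes how much a region's connectivity
profile reconfigures across windows. For node $k$ with profile
$F_{i,k}$ (row $k$ of window $i$'s correlation matrix, self-entry removed),

$$V_k \;=\; 1 \;-\; \frac{\sum_{i \ne j} \rho_{F_{i,k}F_{j,k}}}{n(n-1)},$$

the mean over ordered pairs of distinct windows of the Pearson correlation
between profiles. $V_k \in [0, 2]$: 0 for a frozen profile, 2 for perfect
anti-correlation. The self-entry is removed before correlating because it is
constant at 1 and would deflate the statistic. The packaged implementation is
vectorized (sliding moments from cumulative sums; the profile-correlation sum
computed as $\lVert S\mathbf{1}\rVert^2$ for column-standardized profiles
$S$); tests require agreement with an explicit double-loop evaluation of the
definition to $10^{-10}$.

**Structural connectivity** divides streamline counts by the mean of the two
endpoint volumes, $2\,c_{ij}/(v_i + v_j)$, removing the tendency of larger
regions to accrue more streamlines. The product convention
$c_{ij}/(v_i v_j)$ is available via `convention = "product"`; the sum
convention is the default because it follows the construction literature this
analysis style descends from.

**Synchronization likelihood** (`synchronization_likelihood()`) is the
alternative dynamic measure: both series are time-delay embedded
($m$ dimensions, lag $L$); for each reference point the critical distance per
channel is the $k$-th smallest distance among Theiler-valid neighbours
($w_1 < |i-j| < w_2$), with $k = \max(1, \mathrm{round}(p_{ref}\,n_{valid}))$;
the SL at that point is the number of joint recurrences divided by $k$. This
normalization makes identical channels score exactly 1 and independent
channels score $\approx p_{ref}$, both verified by tests (the independence
level by Monte-Carlo). Distances are Euclidean on the embedded vectors. An
outer Theiler window larger than the embedded series simply disables the
upper bound, which is what makes the conventional parameter set
($m=25$, $L=20$, $w_1=960$, $w_2=1959$, $p_{ref}=0.05$) executable on short
series in principle; note that $m=25, L=20$ requires at least 482 timepoints,
so toy analyses use smaller embeddings.

## Graph metrics

Connectivity matrices are binarized at a sparsity threshold (default 0.1):
negative entries are discarded and the $K = \mathrm{round}(s\,R(R-1)/2)$
strongest positive edges are kept. Ties at the cut are broken toward the
smaller (row, column) index — an arbitrary but deterministic and documented
rule; the alternative (random tie-breaking) would make reruns
irreproducible. If fewer than $K$ positive entries exist the function reports
the achievable sparsity instead of silently under-thresholding.

Four nodal metrics are computed on the binary graph (via igraph):
betweenness centrality normalized by the $(R-1)(R-2)/2$ unordered pairs,
degree, nodal efficiency (inverse harmonic mean of shortest-path lengths,
unreachable nodes contributing zero), and the local clustering coefficient
(zero below degree 2). Disconnected fragments are expected at sparse
thresholds and are handled by the zero conventions rather than errors. All
four are validated exactly against brute-force oracles (path counting by
adjacency powers, triangle enumeration) on hundreds of random small graphs.

## The two-round cross-validated Lasso

Features are the concatenation of the SC upper triangle, FC upper triangle,
the $R$ temporal-variability values (or the SL upper triangle), and $3R$
tissue densities — $p = R(R-1) + R + 3R$ columns, e.g. 990 at $R = 30$.

*Round 1 (selection).* Subjects are split into $k = 10$ folds (shuffled
partition, seed 42 by default). For each fold a Lasso is fitted on the
training portion with the penalty chosen by internal 5-fold cross-validation
(`glmnet::cv.glmnet`, `lambda.min` — mirroring an automatic-tuning Lasso with
per-fold tuning). Features with non-zero coefficients are recorded; the
selected set is the union across folds.

*Round 2 (prediction).* The same fold partition is reused on the selected
columns only; out-of-fold predictions are aggregated into MAE and RMSE, and
the per-subject brain-age gap is predicted minus chronological age. A final
model refit on all subjects (penalty again by internal cross-validation)
is persisted for `predict()` on new cohorts, and its penalty is reported.

Standardization is glmnet's internal per-fit column standardization, i.e.
always computed within the training data of each fit. If round 1 selects
nothing (plausible under pure noise), `brainage()` falls back to the full
feature set with a warning, while the lower-level `fit_predict_cv()` errors,
as a building block should.

Two properties of this protocol deserve emphasis because the tests exercise
both:

1. **Selection leakage.** Round-1 folds each see 90% of all subjects, and
   the union of selections informs predictions for every subject, so
   round-2 out-of-fold errors are optimistic. This is a faithful property of
   the two-round design, not an implementation defect; the no-signal test
   therefore compares the observed MAE against a permutation null that runs
   the identical protocol, rather than against the naive mean-predictor
   baseline.
2. **Gap-age attenuation.** Any regression of age on noisy correlates
   shrinks predictions toward the mean, so the gap correlates negatively
   with age even when the true planted gap is age-independent. The test
   suite requires this artifact to emerge in simulation, since it is an
   expected signature of unadjusted brain-age models. No age-bias
   correction is applied to the gap, deliberately matching the common
   (uncorrected) variant of the analysis.

## Downstream inference

**Partial correlations** residualize both variables on an intercept plus
covariates (chronological age, a 0/1 gender indicator, education in years)
and correlate the residuals; `method = "spearman"` (the default)
rank-transforms everything first. The default is Spearman because reported
"rho" values in this literature conventionally denote rank correlations and
the small samples favour robustness; Pearson is one argument away.
Significance uses $t$ with $n - c - 2$ degrees of freedom. Missing scores
are handled by listwise deletion per analysis, which reproduces the
per-scale effective sample sizes a real cohort table shows. Families of
tests are corrected by Benjamini–Hochberg FDR at $q = 0.05$; in the
pipeline, behavioral scales form one family and each metric-by-network set
of nodal tests forms its own family.

**Canonical correlation analysis** standardizes both sets, extracts the
first canonical pair (maximum-correlation method, via `stats::cancor`),
scales variates to unit variance with the sign convention $r \ge 0$, and
reports structure coefficients (correlations of each original variable with
its own set's variate — the interpretable loading under collinearity).
Inference permutes the subject indices of one variate vector and recomputes
the correlation, with $p = (1 + \#\{|r_{null}| \ge |r_{obs}|\})/(B+1)$;
the variates are held fixed (no refit per permutation), which is the scheme
the reported analyses describe; refitting per permutation is the more
conservative alternative and can be layered on by calling `cca_first_pair()`
inside a permutation loop.

**Cognitive stratification** labels MOCA $< 18$ as impaired and
$\ge 25$ as intact, excluding the middle band and missing scores. Group
contrasts use the pooled-variance two-sample $t$-test (Welch via a flag).
**k-means classification** standardizes the features, runs k-means with a
fresh random initialization per iteration (default 1000), maps clusters to
groups by the best of the two assignments, and reports the modal accuracy
across iterations, ties broken toward the larger value.

## The synthetic cohort generator

`generate_cohort()` draws cohorts whose statistical structure matches what
the analysis assumes, with every age-dependent component scaled by a single
`signal_strength` knob (0 = pure null):

- **Ages** from a truncated normal, mean 64.41, SD 5.66, range 53–76 years —
  the demographic profile of the emulated community cohort.
- **Planted gap**: each subject's latent *brain age* is chronological age
  plus a Normal(0, `gap_sd` = 4.4 years) gap; 4.4 y puts the gap spread at
  the level implied by reported brain-age RMSEs in cohorts of this age range.
- **Functional connectivity** from a three-factor latent time-series model;
  the first factor's loadings are non-zero on a random 30% subset of regions
  and scale linearly with standardized brain age, so FC carries a sparse,
  decodable age signal.
- **Structural counts** Poisson with a symmetric log-mean (median ≈ 60
  streamlines) and a sparse log-linear brain-age slope on 25% of edges.
- **Tissue densities** linear in brain age on a sparse 30% of
  compartment-region features, with Gaussian noise.
- **Behavioral scales** built from latent z-scores and mapped to integer
  scores matched to the reference cohort's means, SDs and ranges (truncation to the
  printed ranges is deliberate: only those moments and ranges are known).
  Resilience is constructed so its in-sample correlation with the planted
  gap equals the target (default −0.35) *exactly on the latent scale*
  (residual orthogonalization), before integer rounding and truncation
  attenuate it by ~1–2%; this keeps the 100-seed Fisher-interval coverage
  test stable at its nominal level. MOCA loads positively on resilience and
  negatively on the gap, so the impaired stratum has larger gaps and lower
  resilience, and the two-group k-means problem is genuinely informative.
  Per-scale missingness follows the reference cohort's per-scale sample sizes;
  the three resilience subscales share the instrument's missingness mask.
- **Exclusion flags** (missing imaging, head motion, depression screen) are
  drawn independently per rule at the reference cohort's recruitment rates.
  The depression-screen threshold is exposed as a parameter rather than
  hard-coded: geriatric depression screening cutoffs are applied
  inconsistently across studies (exclude above 5 versus exclude at or above
  5), and the generator does not guess a convention.

The generator records which feature columns truly depend on brain age
(`attr(cohort, "planted_features")`), enabling selection-precision tests
against a no-signal baseline.

Calibration of the fixed effect-size constants (density slope 0.035, SC
log-slope SD 0.2, FC modulation 0.6) was done once, to place the default
cohort in the qualitative regime of real studies: moderate age decodability
rather than near-perfect recovery, and a clearly negative gap–age
correlation. These constants are not exposed as user knobs to keep "the
study conditions" a single well-defined object.

**What the generator does not emulate**: autocorrelated BOLD dynamics, head
motion and scanner artifacts, spatial autocorrelation of atlas regions,
non-Gaussian questionnaire distributions (floor/ceiling effects beyond
truncation), informative missingness, and the coupling of exclusion flags to
the data. Passing tests therefore demonstrate that the *pipeline* recovers
planted structure under its own assumptions, not that those assumptions hold
in any real cohort.

## Numerical choices and degenerate inputs

- Constant time-series columns, constant connectivity profiles, zero-variance
  residuals, rank-deficient CCA sets and empty cognitive groups raise
  descriptive errors naming the offending region/window/variable.
- Temporal-variability equality between the vectorized and loop paths is
  required to $10^{-10}$; symmetry of all connectivity outputs to
  $10^{-12}$; CCA against the eigenvalue oracle to $10^{-8}$ (the
  generalized eigenproblem is less well-conditioned than the QR route used
  by `cancor`).
- Sliding-window moments use cumulative sums; at the magnitudes of
  standardized imaging data (|x| ~ 1–10) this loses no relevant precision.
- `..pad`: glmnet requires two columns, so a single selected feature is
  padded with an all-zero column whose coefficient is structurally zero.
- Matrices are written at 17 significant digits so disk round-trips are
  bit-exact.
- All fold partitions and permutations are seeded; package functions restore
  the caller's RNG state.

## Problem sizes used by the tests

The default test suite exercises cohorts up to $n = 500$ subjects at
$R = 30$ regions and $T = 265$ timepoints (the planted-association recovery
suite runs 50 such cohorts end to end), graph-metric oracles on 500 random
graphs of up to 8 nodes, 1000-draw closed-form suites for partial
correlation and FDR, and 200-replicate permutation-uniformity checks at
$B = 500$. These sizes were chosen to give each statistical check real
power while keeping a full run in the minutes range on a single core;
$R = 30$ rather than an atlas-scale 246 keeps the feature dimension at 990,
which preserves the $p \gg n$ character of the real problem at desk scale.

## Known limitations

- The two-round protocol's selection leakage (above) means reported MAE/RMSE
  are optimistic relative to a fully nested selection; the package
  implements the protocol as described rather than the nested variant.
- At desk scale ($R = 30$, $n \approx 100$) the leakage is proportionally
  stronger than at atlas scale, so synthetic accuracy tends to exceed the
  reported accuracy of comparable real analyses; attenuation artifacts are
  unaffected.
- The k-means accuracy under the null is not 0.5: best-of-two cluster-label
  matching inflates chance agreement by $O(n^{-1/2})$, which the null test
  quantifies by Monte-Carlo instead of assuming.
- Canonical correlations on small samples with listwise deletion are upward
  biased; the permutation p-value, not the magnitude of $r$, carries the
  inference.
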
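---
title: "Methods: gradients, equivolumetric profiles, longitudinal contrasts and prediction"
author: "gradplast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gradients, equivolumetric profiles, longitudinal contrasts and prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gradplast implements a longitudinal analysis of cortical functional
organization and depth-varying microstructure for crossover mental-training
studies, together with synthetic-data generators that plant ground truth for
every stage. This vignette is the package's account of the underlying
models, the parameters that matter, the numerical choices, and what the
synthetic tests do and do not establish.

## Functional gradients and eccentricity

A parcel-by-parcel functional connectivity matrix is reduced to a
low-dimensional embedding in four steps.

1. **Row-wise proportional thresholding** (`thresholdRows`). Each row keeps
   its `ceil(density * (n - 1))` largest off-diagonal entries; the default
   density of 0.10 zeroes 90% of every row. Ties at the retention boundary
   are broken by (value descending, column index ascending) so results are
   identical across platforms. The output is asymmetric by construction;
   symmetry is restored by the affinity step.
2. **Normalized-angle affinity** (`normalizedAngle`):
   `a_ij = 1 - arccos(cos(row_i, row_j)) / pi`, bounded in [0, 1], 1 for
   identical rows, 0.5 for orthogonal rows. This affinity is insensitive to
   the scale of the retained connectivity values, depending only on the
   pattern of suprathreshold connections.
3. **Diffusion map embedding** (`diffusionEmbedding`). With affinity `A`,
   degree `D`, the kernel `W = D^-alpha A D^-alpha` controls the influence
   of the sampling density (`alpha = 0.5` by default, the anisotropic
   normalization that is robust to noise while retaining global geometry);
   the transition operator `P` row-normalizes `W`. Eigenvectors are computed
   on the symmetric conjugate `Dw^-1/2 W Dw^-1/2` (numerically stable
   symmetric eigensolver) and back-transformed; each eigenvector is
   normalized so the trivial constant eigenvector is exactly 1, then
   dropped. At diffusion time `t = 0` (the default) the multiscale
   convention scales component i by `lambda_i / (1 - lambda_i)`, summing the
   diffusion operator over all scales; a plain-eigenvector mode is available
   and flagged in the embedding's provenance. Variance explained is reported
   as `lambda_i^2 / sum(lambda^2)` over all nontrivial eigenvalues. Ten
   components are computed by default and the first three (G1, G2, G3) are
   interpreted.
4. **Procrustes alignment** (`procrustesAlign`). Individual embeddings are
   mapped onto a reference embedding by the orthogonal (rotation/reflection)
   transform minimizing Frobenius distance -- no scaling or translation, so
   within-embedding pairwise distances are untouched and eigenvalues remain
   meaningful. The package ships no empirical group template: any reference
   embedding can be supplied, and the pipeline builds a synthetic reference
   from the noise-free generative kernel.

**Eccentricity** (`eccentricity`) is the per-parcel Euclidean distance of
(G1, G2, G3) from the center of the 3D gradient space -- the across-parcel
centroid by default (per-subject centroid when applied per subject), with
the origin of the aligned space available as an alternative, since either
reading of "individual center" is defensible. Scores enter eccentricity on
their lambda-scaled (multiscale) scale, consistent with the embedding
convention; this choice is recorded in the embedding parameters. Low
eccentricity is read as functional integration, high as segregation.

## Equivolumetric depth profiles

Cortical folding changes the cross-sectional area of a cortical column
between the white and pial surfaces, so surfaces at fixed *distance*
fractions do not sample fixed *volume* fractions. When the area varies
linearly from `A_in` (white) to `A_out` (pial), the cumulative volume below
distance fraction `rho` is the quadratic
`V(rho) = A_in rho + rho^2 (A_out - A_in) / 2`, and the surface enclosing a
volume fraction `alpha` sits at

`rho(alpha) = (-A_in + sqrt(alpha A_out^2 + (1 - alpha) A_in^2)) / (A_out - A_in)`,

with the analytic limit `rho = alpha` when `A_out = A_in` (taken explicitly
when the areas differ by less than 1e-9 relative, avoiding the 0/0).
`vertexAreas` assigns each vertex one third of its incident triangle areas,
so vertex areas sum exactly to the mesh area.

`buildLaminarStack` places 12 intracortical surfaces at volume fractions
`alpha_i = i/13` -- strictly interior, excluding the pial and white
boundaries; the midpoint rule `(i - 0.5)/12` is selectable because the
boundary-inclusion convention is not standardized. Vertices move along the
straight segment joining linked white/pial vertices (the linked-vertex
setting; no streamline solving). Two orientation conventions coexist and
both are recorded: volume fractions are measured from the white surface,
while depth indices run 1 (superficial, pial-adjacent) to 12 (deep), so that
the superficial/middle/deep compartments are depths 1-4, 5-8 and 9-12.

Sampling (`sampleField`) evaluates analytic fields exactly and voxel
volumes by trilinear interpolation (nearest-neighbour selectable);
out-of-bounds vertices are marked missing, and more than 5% missing aborts
the run. Parcel profiles are plain means over assigned, non-missing
vertices; parcels with fewer than 10 valid vertices are flagged
low-confidence. Depth-wise z-scores use the population (n) denominator, so
a two-parcel column standardizes to exactly -1, +1.

## Longitudinal mixed-effects contrasts

Change maps are differences of subsequent-timepoint maps within subject;
the module trained during the interval labels the row, untrained retest
intervals carry `None`. Per parcel, the model is

`delta ~ 1 + age + sex + intervalIndex + tm + (1 | subject)`

fit by restricted maximum likelihood. Age is centered (affects only the
intercept); `intervalIndex` (scans since baseline) absorbs test-retest
effects and can be toggled off. Because the design matrices are shared by
all parcels, the package rotates the data once by a per-subject orthonormal
basis whose first vector is constant: the random-intercept covariance
becomes diagonal in that frame, and each parcel reduces to a
one-dimensional REML optimization over the variance ratio with weighted
least squares -- thousands of parcels fit in seconds, with estimates
matching a general mixed-model solver to numerical precision (the test
suite cross-checks against lme4). A zero between-subject variance estimate
is a boundary (singular) fit and simply floors the ratio at 0 (OLS); zero
residual variance is an error.

Inference uses Wald t statistics with the residual degrees of freedom of
the fixed-effects design, `df = n - p` (the convention of vertex-wise
surface statistics toolboxes), and the effect size `d = t / sqrt(df)`. The
two conventions are mutually consistent: independently reported (t, d)
pairs from a design of this family imply a common df under this definition,
which the acceptance suite verifies. Satterthwaite-style df are deliberately
not used; with hundreds of observations the difference is negligible and
the simple convention is what the reported effect sizes imply. p values are
corrected across parcels within one contrast by Benjamini-Hochberg
(`fdrBH`, 400 tests at default parcellation); no correction is applied
across contrasts.

## Spin permutation tests

Spatial correspondence between two parcel maps is a Pearson correlation
whose null must respect spatial autocorrelation: smooth maps produce large
|r| by chance and a parametric test over-rejects badly (the calibration
check measures both). `spinTest` builds the null by rotating parcel
centroids on the sphere with Haar-uniform rotations (QR of a Gaussian
matrix with sign correction, reflected onto SO(3); moment checks verify
uniformity) and re-assigning the first map by nearest rotated centroid.
With a hemisphere factor, the right hemisphere receives the x-mirrored
rotation, the standard convention. The p value follows the permutation
counting rule `p = (1 + #{|null| >= |obs|}) / (nPerm + 1)`, two-sided by
default (one-sided available); defaults are 1000 rotations. Permutation
index vectors depend only on the parcellation, so `spinPermutations`
precomputes them once and reuses them across map pairs.

## Behavioral prediction

Five a-priori networks times seven brain-change metrics (eccentricity,
G1-G3, and superficial/middle/deep qT1 compartments) give 35 candidate
features per subject. Per cross-validation fold:

1. **In-fold nuisance removal**: each feature is regressed on (1, age, sex)
   using training rows only; training betas are applied to the test rows.
   Age and sex are never candidate predictors.
2. **Sequential selection**: greedy forward selection of
   `ceil(0.2 * 35) = 7` features, scored by training-set mean absolute
   error of a lasso at a fixed mid-grid penalty (0.01, the geometric
   midpoint of the [1e-4, 1] grid). The greedy pass deliberately uses no
   inner cross-validation; the penalty is re-tuned after selection. The
   greedy scorer runs on a precomputed Gram matrix, so the quadratic number
   of candidate fits costs microseconds each (the implementation is
   verified against glmnet).
3. **Lasso with inner CV**: penalty chosen on a 100-point log grid over
   [1e-4, 1] with L1 ratio 1 by inner 5-fold cross-validation, refit on the
   full training rows, applied to the test rows.

Folds are assigned by random shuffling (no stratification variable is
defined for this design); per-repeat seeds derive from the master seed, so
results are bit-reproducible given (seed, data). Per repeat the package
reports the pooled-prediction Pearson r, the fold-averaged r, and the
negative mean absolute error on the behavior's native scale (no
normalization -- nMAE magnitudes scale with the behavioral units).

A caveat that matters for null calibration: pooled cross-validated r is
negatively biased under the null, because each fold's prediction intercept
is the training mean, which is anti-correlated with the held-out fold mean.
Fold-averaged r does not have this channel (folds whose predictions are
constant are scored r = 0: a constant prediction carries no signal). The
package therefore emits both, and its null-calibration checks (shuffled
targets, the leakage guard) assert on the fold-averaged statistic.
Specificity controls (`specificityTests`) rerun the identical pipeline on
shuffled and off-domain targets with the same repeat seeds and compare
repeat-wise r by a paired sign-flip permutation test.

## The synthetic-data generators

The generators define the study conditions under which the package is
tested; they are first-class, tested code.

* **Connectomes** (`makeLatentManifold`, `makeConnectome`): parcels on a
  radially jittered unit sphere (jitter SD 0.05), edge weights
  `exp(-d^2 / 2)` plus symmetric Gaussian noise (SD 0.01 by default),
  clipped to [-1, 1], unit diagonal. The sphere is the natural stand-in for
  cortex -- a closed 2D sheet -- and its leading diffusion eigenfunctions
  are linear in the coordinates, so the full gradient pipeline (threshold at
  0.10, normalized angle, embedding) should recover the planted geometry;
  the acceptance suite requires Procrustes congruence of at least 0.95 at
  400 parcels. A cube-filling latent cloud was considered and rejected: after
  row thresholding the kernel reduces to a k-nearest-neighbour graph whose
  eigenfunctions warp the axes, capping congruence around 0.93 regardless of
  kernel scale.
* **Cohorts** (`makeCohortDesign`, `makeCohortMaps`): TC1 trains
  Presence-Affect-Perspective, TC2 Presence-Perspective-Affect, RCC
  nothing; 100 subjects per arm by default, ages uniform 20-55, sex
  Bernoulli(0.59), used only as nuisance. Maps accumulate per interval:
  planted module effect + per-subject random intercept (SD 0.1) + residual
  noise (SD 0.1), all additive on the metric scale with no module-by-age
  interactions (none are modeled in the contrasts either). Change scores
  therefore follow exactly the random-intercept model the contrast stage
  fits.
* **Cortex fixtures** (`makeCortex`): flat sheets, wedges (pial stretched
  along one axis so area varies linearly with depth -- the regime in which
  the closed-form equivolume fraction is exactly volume-preserving),
  spherical caps, and sinusoidally folded sheets, all with linked vertices
  and shared topology. qT1 fields are analytic functions of space, with
  optional rasterization to a voxel volume that agrees at voxel centers.
* **Behavior** (`makeBehavior`): `y = Xw + noise` with a sparse
  (7-of-35) weight vector.

What the generators do *not* emulate: measurement of connectivity from BOLD
time series (and its autocorrelation and motion structure), registration
and segmentation error in surfaces, partial-volume effects in qT1, dropout
mechanisms beyond missing-at-random rows, or module-by-covariate
interactions. Passing tests therefore establish that the machinery is
correct and calibrated under its own assumptions -- not that those
assumptions hold in any empirical dataset.

## Problem sizes and numerical tolerances

The test and acceptance runs use: 400 parcels for manifold recovery; 2000
parcels x 300 subjects for null calibration of the contrasts (rejection at
p < 0.05 must fall in [0.040, 0.060]); 200 parcels for planted-effect
recovery at population d = 0.25 (the planted contrast magnitude is derived
analytically from the design's GLS standard error); 500 replicate map pairs
x 500 spins for spin calibration; and n = 100 subjects, 5 folds x 20
repeats for the prediction checks. These sizes make the whole acceptance
computation run in about a minute on one core while keeping Monte-Carlo
error well inside each criterion's band. Embedding-vs-oracle agreement is
required to 1e-8; the equivolume root to 1e-10; volume conservation to 1e-3
relative.

One prediction-stage property deserves honesty: with the planted signal at
population R^2 = 0.3 spread over 7 equal, independent features (n = 100),
the greedy pass recovers a median of 4 of 7 true features, not 5 -- the
per-feature correlation (~0.21) is simply too close to the noise floor of
28 competitors at 80 training subjects. Support recovery at the 5-of-7
level emerges around R^2 = 0.5 (the high-SNR regime where lasso-style
selection is consistent), which the unit suite demonstrates at R^2 = 0.7.
Out-of-sample r, by contrast, is reliably positive at R^2 = 0.3, because
prediction pools the signal the selector does find. Making the informative
features mutually correlated raises r further but *lowers* support
recovery (the greedy pass picks one proxy for the shared factor), so the
independent-feature design is kept.

## Known limitations

* The mixed model supports a single random intercept per subject; random
  slopes and crossed random effects are out of scope.
* Vertex-level (non-parcellated) gradients and alignment across different
  parcellations are not supported.
* The spin test assumes parcels are adequately summarized by spherical
  centroids; variogram-matching surrogates would be the extension for
  irregular geometries.
* Self-intersection of equivolumetric surfaces in thin, sharply folded
  meshes is permitted and only counted, not repaired.
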
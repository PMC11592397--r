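---
title: "Methods: robust PET radiomics survival modeling with petrad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: robust PET radiomics survival modeling with petrad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, the reasoning
behind its defaults, and the limits of what its green tests establish.

## 1. The modeling problem

Radiomics models for PET are fragile in two specific ways: the volume of
interest depends on who (or what) delineated it, and texture features
depend on discretization and resampling choices. `petrad` implements a
workflow that measures that fragility explicitly — five contour variants
and six extraction-parameter sets per lesion — screens features by
ICC(2,1), and only then lets a nested cross-validated elastic-net Cox
model select a small signature (seven features) for survival stratification
and one-year-survival classification.

## 2. Synthetic cohort: the stated world

No patient data ship with the package; every claim is tested on synthetic
cohorts whose ground truth is known.

**Phantom.** A subject is a 3D SUV-scaled volume containing one spherical
lesion. Inside the sphere of radius $R$ the expected uptake is
$\mathrm{SUV}_{max}\cdot p(r)\cdot t(\mathbf{x})$ with a parabolic radial
profile $p(r) = 1-(1-e)(r/R)^2$ ($e$ = `edge_fraction`) and a
multiplicative texture field $t$: white noise smoothed with a Gaussian
kernel of physical scale `texture_scale_mm`, rescaled to
SD `heterogeneity_sd` and clipped at $1 \pm 3\,$SD. The product is
renormalized to a maximum of 1 over the lesion, so the realized lesion
maximum equals `suv_max` exactly when `noise_sd = 0`; this keeps
`lesion_suvmax()` and the threshold contours analytically checkable.
Background is constant (`background_suv`) and i.i.d. Gaussian noise is
added everywhere.

Defaults: 3 mm isotropic voxels (PET in-plane resolutions of the emulated
regime run 2.7–5.5 mm), lesion radius 15 mm, SUVmax 10 against background
1, noise SD 0.2 SUV. `texture_scale_mm = 3`: the texture correlation
length must sit well below the lesion radius, otherwise a single lesion
contains only a couple of independent texture patches and its *realized*
heterogeneity is sampling noise rather than a function of the
`heterogeneity_sd` knob — which would contradict the design goal that
GLCM/GLSZM features respond monotonically to the knob. Three millimetres
(about one voxel; sub-centimetre intratumoral heterogeneity) makes the
knob identifiable at realistic lesion sizes.

**Survival.** Subject $i$ draws latent lesion parameters (heterogeneity,
SUVmax, radius, uniform over fixed ranges) which are standardized with
their theoretical moments into $x_i$; the event time is exponential with
hazard $\lambda_0\exp(\beta^\top x_i)$. The default planted effect is
$\beta_{\text{het}} = 1.2$ ("strong": $|\beta|\ge 1$). $\lambda_0$ derives
from the target one-year death fraction (default 0.55, typical of stage
IVB NSCLC) as $-\log(1-0.55)/365$. Censoring is an independent exponential
calibrated so about `censoring_rate` (default 0.2) of subjects are
censored under the null. Times are rounded up to whole days — ties are a
deliberate feature of the stated world and the reason the Cox likelihood
uses Breslow tie handling. The one-year label is *derived*
(`event == 1 & time <= 365`), never simulated separately, so the two
endpoints cannot disagree; a subject censored before day 365 is labelled
alive-at-one-year, a conservative convention.

**Clinical covariates** follow the published marginal frequencies of the
emulated 99-patient cohort (59/40 female/male, 76/23 ever/never smokers,
M1a/M1b/M1c 22/13/64, four first-line regimens 56/30/9/4, four histologies
79/15/3/2, ages 30–88 with median near 67); laboratory values use
field-typical means (BMI 26.5 ± 5.5, platelets 280 ± 90 × 10³/µL,
neutrophils 5.5 ± 2.2 × 10³/µL). These exist to exercise the one-hot /
min-max preprocessing realistically, not to carry signal.

**What the generator does not emulate:** scanner point-spread functions,
attenuation or reconstruction artifacts, respiratory motion, multiple or
non-spherical lesions, correlated clinical covariates, or informative
censoring. A green recovery test therefore establishes that the *workflow*
can find a planted texture signal of realistic strength at $n = 99$ — not
that any particular clinical signature is real.

## 3. Segmentation

Threshold contours keep the largest 26-connected component of
$\{v \ge f\cdot \mathrm{SUV}_{max}\}$ touching the seed region (closed
comparison; component ties broken by seed overlap, then lexicographic
centroid). Constraining to one component is a documented choice — the
emulated protocol does not say whether its threshold masks were so
constrained. The two manual-perception contours have no operator here and
are deterministic surrogates: `ct_perception` is the true lesion support
(anatomical truth as a proxy for CT-window volume perception) and
`pet_perception` dilates the 40 % contour by one voxel and flips boundary
voxels off with probability 0.2 under a seed (emulating blur- and
display-driven variability).

## 4. Feature extraction

* **Discretization**: fixed bin *width* (the emulated grid is {5, 25, 75}
  intensity units), anchored at the per-VOI minimum:
  $\ell(x) = \lfloor x/W\rfloor - \lfloor \min/W\rfloor + 1$. Anchoring at
  the minimum is the dominant convention for fixed-width binning; the
  source protocol is silent.
* **Texture matrices**: GLCM (13 unique 3D directions, symmetrized,
  normalized per direction, matrices averaged, 24 features), GLRLM (13
  directions, count matrices averaged, 16), GLSZM (26-connected zones,
  16), NGTDM (26-neighbourhood means, 5), GLDM (dependence $\alpha = 0$,
  neighbour counted when $|\Delta\ell|\le\alpha$, plus the centre, 14).
  "Averaged" was read as matrix-level averaging (normalize per direction,
  average, compute once); feature-level averaging is the other defensible
  reading. Every family is verified against brute-force enumeration
  oracles written as independent scalar loops (tolerance 1e-10 on 200
  random images), and rotation/shift invariances are property-tested.
* **Degenerate conventions**: single gray level ⇒ GLCM Correlation and
  MCC 1, information measures 0; zero variance ⇒ skewness/kurtosis 0;
  constant region ⇒ NGTDM busyness/contrast 0 and coarseness capped at
  1e6; single-voxel masks ⇒ axis lengths 0 with elongation/flatness 1.
* **Filtered images**: one-level separable Haar DWT (decimated; even axis
  lengths make it orthonormal so subband energies sum exactly to the input
  energy; odd axes are symmetrically padded). Haar was chosen over longer
  wavelets precisely to keep that Parseval check exact. Subband masks are
  the 2×2×2 block-OR of the original mask. LoG filters at physical scales
  (default 2 and 4 mm) use separable Gaussian smoothing and a
  reflect-boundary discrete Laplacian whose total response is exactly
  zero. Shape features are geometry-only and computed once per mask.
* **Surface mesh**: meshing the *raw* binary indicator at midpoints
  overestimates a digital ball's area by 25–30 % (staircase effect), which
  would push sphericity far from 1. The mesher therefore triangulates the
  0.5-isosurface of the indicator after mild Gaussian anti-aliasing
  (σ = 0.8 voxels), via a six-tetrahedron cell decomposition with linear
  interpolation; digital-ball sphericity lands at 0.98–0.995 (tested).
  Masks whose smoothed peak falls below 0.5 fall back to the raw
  indicator.
* The feature count under the full default configuration is 1037
  (11 image variants × 93 intensity features + 14 shape). The emulated
  protocol's 924 is not reconstructable from its text (unknown LoG sigma
  count and shape handling); the schema is configuration-driven instead.

## 5. Robustness screening

ICC(2,1) is computed from the exact two-way ANOVA decomposition;
`icc21()` is oracle-tested against explicit sums and against `aov()`.
Features with zero total variance are perfectly reproducible constants:
they receive ICC 1 with a degenerate flag, are kept, and stay in the
denominator of the summary percentage. Robustness uses the strict
inequality ICC > 0.75, with one boundary exception: features with ICC
exactly 1 survive any threshold up to 1 (so "only perfect features
survive" holds at threshold 1.0 despite the strict rule). The two
screening families (six extraction configs; five contours) are screened
independently and intersected. Whether screening should use all subjects
or only the training split is unspecified in the emulated protocol; the
default screens all subjects, and the choice is a function argument.

## 6. Survival modeling

* **Split**: `round(n × 0.2)` held out (99 → 79/20), stratified on the
  one-year outcome jointly with a key categorical, falling back to
  outcome-only when a stratum is too small; allocation by largest
  remainder so event proportions differ by at most one subject.
* **Preprocessing**: min–max parameters and one-hot category sets are
  learned on the training split only. Test values outside the training
  range extrapolate beyond [0, 1] (not clipped); unseen categories encode
  as all zeros with a warning; constant columns map to 0 with a warning.
* **Elastic-net Cox** is delegated to `glmnet` (Breslow ties, internal
  standardization for the penalty, coefficients on the original scale).
  The regularization path runs from the data-driven maximum down by the
  `alpha_min_ratio` knob, log-spaced.
* **Nested selection**: outer 5-fold (event-stratified); within each outer
  training set, `inner_repeats` (default 10) repetitions of 5-fold CV grid
  search over (`l1_ratio`, `alpha_min_ratio`, path position) scored by
  validation concordance; the refit at the winning point contributes its
  non-zero coefficients ranked by |β|. The seven most frequent features
  across repetitions (ties: larger mean |β|, then name order) form the
  fold's model, refit with a tiny ridge (1e-6) for numerical stability and
  scored on the outer fold. The best outer fold's model is carried forward
  *without* refitting on all 79 — the literal reading of the emulated
  workflow — and evaluated once on the held-out 20. A refit toggle is
  deliberately absent from the default path.
* **Evaluation**: mean-split risk groups (ties at the mean go to low
  risk, since only scores *above* the mean are high-risk), product-limit
  curves, the standard two-group logrank statistic with hypergeometric
  variance (χ², 1 df), and Harrell's C with the `survival::concordance`
  conventions (pairs tied on event time are not comparable; a subject
  censored at another's event time counts as surviving longer; score ties
  count ½).

## 7. One-year classification

The balanced random forest is implemented from scratch (no forest package
is available in the target environment): every tree sees a class-balanced
bootstrap ($n_{\min}$ draws with replacement from each class), CART
splitting with gini or entropy impurity, per-node feature subsampling
(`sqrt` or a fraction), and leaf class probabilities averaged across
trees. Hyperparameters are grid-searched by stratified 5-fold CV on AUC
(ties to the first grid point) and refit on the full training set; the
default grids are max_depth {3, 5, ∞}, n_estimators {100, 300},
min_samples_split {2, 5}, min_samples_leaf {1, 3}, max_features
{sqrt, 0.5}, criterion {gini, entropy} — the emulated protocol names the
knobs but not the ranges. Each variant uses exactly the seven features its
survival model selected. The positive class is deceased-at-one-year: that
orientation makes the printed sensitivity/specificity/accuracy triple of
the emulated study internally consistent on a 20-patient split (the unique
reconstruction is P = 11 deceased / N = 9 alive). Reports carry both plain
and balanced accuracy, because the emulated study prints a second accuracy
triple it never labels; the package does not guess which it is.

## 8. Numerical and scale choices in the acceptance experiments

The statistical acceptance properties fix cohort size (99), seed counts
(20 recovery / 50 null-concordance / 200 logrank-calibration replicates),
the selection size (7) and all thresholds. The knobs they do not fix were
set once for tractability on one CPU: recovery phantoms use 20×20×12
voxels at 3 mm, radius 12 mm, `edge_fraction` 0.7 (a flatter uptake
profile so texture rather than the radial profile dominates intra-VOI
variance), bin width 0.5 SUV, feature classes {firstorder, glcm, glszm} on
the original image, and a reduced CV grid (l1_ratio {0.5, 0.9},
alpha_min_ratio 0.05, 10-point paths, 3 inner repeats). A "planted-feature
proxy" is operationalized per cohort as any feature whose Spearman
correlation with the true heterogeneity parameter exceeds 0.5 in absolute
value. Null-calibration replicates use tabular cohorts
(`make_volumes = FALSE`): the property under test concerns the statistical
pipeline (fit on train, mean-split and logrank on test), not image
synthesis. One printed-value caveat: the χ² = 16.18 statistic is itself
rounded to two decimals, and exact arithmetic at 16.18 gives
p = 5.760e-5 while the printed p (5.77e-5) matches the unrounded
statistic; the acceptance check asserts agreement within the
input-rounding band.

## 9. Known limitations

Shape surface area is an anti-aliased isosurface estimate (1–2 % accuracy
on digital balls), not the exact marching-cubes mesh of any reference
implementation; NRRD support covers axis-aligned geometry and the scalar
types the pipeline writes; DICOM ingestion, PH diagnostics, competing
risks, ICC confidence intervals and calibration curves are out of scope.
Configuration files are JSON rather than YAML (no YAML parser in the
target environment). The external-reference cross-validation of feature
definitions could not be run offline (the reference radiomics library is
not installed); the brute-force oracles stand in for it, so agreement with
any specific third-party implementation's conventions (e.g. feature-level
direction averaging) is not established.
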
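---
title: "Methods: appearance models, rating reliability, and face-space prediction"
author: "faceforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: appearance models, rating reliability, and face-space prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faceforge)
```

# The problem

People form first impressions of a face within a fraction of a second, and
different observers agree on these impressions to a striking degree. This
package implements a complete analysis chain for studying that phenomenon
quantitatively:

1. a **statistical appearance model** turns landmark-annotated face images
   into low-dimensional component scores ("face-space" coordinates);
2. **judge ratings** of traits (friendly, dominant, attractive, ...) on a
   1–9 Likert scale are averaged per ratee and their reliability measured
   with Cronbach's α;
3. mean ratings are **correlated with self-reported personality** scores
   (1–10 scale), with significance from a permutation test, including the
   individual-judge analysis that shows why group-level correlations
   overstate what any single observer can infer;
4. mean ratings are **predicted from the facial components** by linear
   regression with correlation-based feature selection under repeated
   20-fold cross-validation;
5. **extreme faces** are synthesized by pushing the regression-selected
   components to ±4 SD, and a forced-choice validation statistic tests
   whether observers pick the extreme face over random faces.

Because face photographs of real cohorts are not freely distributable, the
package ships a fully parametric **synthetic-cohort generator** whose
ground truth is known; every stage of the pipeline is exercised against
that ground truth.

# The appearance model

## Shape

Each face is an ordered set of 2-D landmarks (the same anatomical point in
every face occupies the same row). Generalized Procrustes analysis removes
translation, rotation and uniform scale: shapes are centred, scaled to unit
centroid size, rotated onto the current mean, and the mean is re-estimated
until it changes by less than `1e-8` RMS (`align_shapes()`). The mean is
renormalised to unit centroid size each iteration and finally rotated onto
the first input shape, so the result does not depend on input order.

Two numerical choices deserve note:

* **Tangent-space scaling.** When a single shape is fitted onto the mean
  (`procrustes_fit()`), the scale is chosen so that the aligned shape's
  projection onto the mean equals the mean's squared norm, rather than the
  least-squares scale. With least-squares scaling, a shape `mean + d` with
  `d` orthogonal to the mean comes back shrunk by `1 + ||d||²`; with the
  tangent projection it comes back exactly. This is what makes the
  synthesize→project round trip exact for shape coefficients.
* **Axis sign convention.** Every principal axis is oriented so its
  largest-magnitude loading is positive, which makes component signs
  deterministic across platforms and BLAS libraries.

The shape PCA (`fit_shape_model()`) uses the SVD of the centred data matrix
with the n−1 variance divisor and keeps the smallest number of components
whose cumulative explained variance reaches `variance_retained`
(default 0.95; the retention rule is a threshold, and the resulting
component count is data-dependent).

## Texture

Texture is modelled shape-free: every image is warped from its own
landmarks onto the mean shape and the pixels inside the face mesh are
collected into one vector per face (`extract_textures()`), followed by a
second PCA. The warp is piecewise affine over a Delaunay triangulation of
the mean shape (computed once per model via `deldir` and canonicalised for
determinism); each output pixel is mapped through its triangle's
barycentric coordinates and the source image is interpolated there.

Interpolation and frame resolution are the accuracy-limiting choices:

* the model pipeline samples with the **Catmull-Rom cubic** kernel rather
  than bilinear interpolation. A face passes through two resamplings on the
  synthesis→projection round trip, and bilinear interpolation loses enough
  energy at feature edges that texture coefficients came back 3–25% off;
  with the cubic kernel and the oversampled frame below, the error is
  ~0.4%. `warp_image()` itself defaults to bilinear (and guarantees no
  intensity overshoot in that mode); "cubic" and "nearest" are selectable
  everywhere.
* the shape-free frame **oversamples the input resolution 3×**
  (`frame_scale = 3`), because resampling loss scales with feature size in
  pixels. Measured on the three-factor recovery cohort, the texture
  round-trip error is 1.4% at 2× and 0.35% at 3×.
* before any warp, the masked texture is **padded outward** by a few
  dilation passes (`extend_image()`), so interpolation at the mesh boundary
  never mixes in the background fill. Without this, boundary pixels
  contaminate every texture by up to a quarter of a component SD.

Extracted textures are clamped to the image range [0, 1] (trimming cubic
overshoot), which also keeps the mean texture valid so that the mean face
(`synthesize_face()` at `c = 0`) reconstructs exactly.

## Component scores

A face's representation is the concatenation of its standardized shape and
texture coefficients (each coefficient divided by its component SD). Across
a training set these scores have mean 0, SD 1, and are uncorrelated within
each block. One model is fitted per gender: male and female facial
composition differs enough that a pooled model mixes gender into every
component.

# Ratings and reliability

Judge scores are integers 1–9 with the neutral answer at 5; the per-ratee
mean over its ~20 judges is the trait score used downstream. Cronbach's α
is computed with **judges as items and ratees as cases**:
`α = k/(k−1)·(1 − Σ var(judge) / var(total))`.

The rating design is incomplete — each ratee has its own panel of ~20
judges, and no complete judge × ratee cross exists — so a literal α is
undefined. The default scheme (`reliability(..., scheme = "subsample")`)
builds a pseudo-complete matrix per trait × gender: with k the minimum
panel size, k scores per ratee are subsampled and shuffled into k "judge
slots" (seeded, reproducible). Because slots mix different judges, the
judge-bias variance stays in the error term, which is conservative. A
variance-components alternative (`scheme = "icc"`: Spearman–Brown applied
to ICC(1) from the one-way ANOVA decomposition) gives closely similar
values on the synthetic cohorts and is available for sensitivity checks.

Trait-trait structure is summarised two ways: a network of pairwise
Pearson correlations per gender (edges kept at p < .01, two-sided t test;
scope marks whether an edge is significant for women, men, or both), and
average-linkage hierarchical clustering on distance 1 − r cut at k = 3
(ties resolved deterministically by lexicographic trait order). Gender
contrasts use Welch's unequal-variance t test with Welch–Satterthwaite
degrees of freedom.

# Personality associations

Correlations between mean ratings and personality scores are computed on
the intersection of ratees with both data types (pairwise deletion, no
imputation). Significance uses a permutation test with 10,000 repeats by
default: the personality vector is permuted, the ratings stay fixed, the
statistic is |r| (two-sided), and the p-value uses the add-one convention
`(1 + #{|r_perm| ≥ |r_obs|}) / (n_perm + 1)`, so p is never exactly zero.
The display mask keeps cells with |r| ≥ 0.20 and p < .01.

The **individual-judge analysis** recomputes each correlation per judge on
only the ratees that judge rated (minimum panel 4; constant-scoring judges
are excluded and counted), then summarises the per-judge correlations by
their mean, SD and a normal-approximation 95% interval. On any cohort with
judge noise, the group-level correlation on averaged ratings exceeds the
mean judge-level correlation — averaging cancels judge error, individual
scores do not — which is why group-level effect sizes must not be read as
individual-level effects.

# Predicting ratings from facial components

The predictor matrix is the concatenated standardized shape+texture score
matrix. For a given trait:

* within each cross-validation fold, components are ranked by |Pearson r|
  against the training rows only (ties to the lower index) and models with
  a growing number of the top components are fitted by OLS;
* held-out predictions are pooled within a repeat and compared to the
  observed scores by Pearson r (per-fold averaging is available via
  `pooling = "per_fold"`; pooling is the default because 20-fold test sets
  are small);
* the best feature count maximises the mean r across repeats; the reported
  SD is the spread of the per-repeat r at that count; a final model is
  refitted on all rows at the best count.

Defaults are 20 folds and 30 repeats with fresh random fold assignments per
repeat (all seeds derived from one master seed); the candidate feature
counts default to `1..min(30, n/5, p)`.

A subtlety worth knowing: with many candidate components, the component
that wins univariate selection does so partly because of its correlation on
the held-out rows of the same finite sample, so a *single* null target can
show cross-validated r of 0.1–0.2 without any true signal. This
winner-selection optimism decays with n. The package's null checks
therefore average over independent null targets (8 draws at n = 400 with
10 components), where the mean sits within ±0.1 of zero; single-draw CV
values on null data should be interpreted with this optimism in mind.

`predict_personality()` runs the identical machinery with a personality
trait as target. On data where personality is only weakly tied to the face,
the resulting r stays low and the RMSE near the target SD — the function
exists to measure exactly that, and a positive control (a strongly
face-dependent synthetic trait) confirms the machinery itself can predict
when signal exists.

# Extreme faces and validation

The regression coefficients define a direction in face-space. In the
default `mode = "saturate"`, every selected component is set to
`sign(β)·4 SD` for the high face and the negation for the low face; all
other components stay at zero. The alternative `mode = "beta_weighted"`
moves along the β direction, rescaled so the largest selected component
sits at 4 SD. The saturating mode is the default because the stronger
reading of "applying four standard deviations to the facial features" is
that each feature saturates; both modes are one flag apart, and
magnitude 2 reproduces the milder single-component displays. The predicted
gap between the pair is exactly `Σ 2·|βᵢ|·4` (in standardized score units),
and the low face's settings are the exact negation of the high face's.

Random comparison faces draw every standardized component from a standard
normal truncated at ±3 SD. The truncation guarantees that the extreme face
remains the most extreme along the trait axis; untruncated draws
occasionally dominate it and would corrupt the validation simulation. The
forced-choice statistic is an exact one-sided binomial test of the count
choosing the extreme face against chance 1/4 (the claim is directional).

`simulate_validation()` is an in-silico stand-in for a human validation
event: each simulated judge perceives each face's trait level as the
regression prediction plus independent normal noise and picks the argmax
(ties uniform). With zero noise the extreme face is always chosen; as noise
grows the choice proportion falls monotonically towards 1/4.

# The synthetic cohort

The generator emulates the structure of a face-rating study without any
photograph: cartoon faces (elliptical head, eyes, brows, nose, mouth)
rendered from 32 landmarks in a 64 × 64 px frame, where five latent factors
— face width, mouth curvature, eye size, brow height, skin tone — displace
the landmarks by fixed per-SD amounts and the shading follows the
landmarks. Defaults: 120 ratees per gender; ~20 judges per ratee; judge
score = `round(clip(5 + loadings·latents + gender offset + judge bias +
noise, 1, 9))` with judge noise 1.5 Likert points and judge-bias SD 0.5
(these place Cronbach's α in the 0.6–0.95 range); personality traits built
as `ρ·factor + √(1−ρ²)·noise` with ρ between 0.20 and 0.32 for five
designated traits, the rest pure noise; small per-face similarity jitter
(≤ ~1.5° rotation, ±2% scale, ±1 px shift) and 0.2 px annotation noise.
Male faces are 0.8 SD wider on average, and four traits carry small
gender offsets, so gender contrasts are recoverable.

Two generator details are deliberate design choices:

* **Exact-moment latent sampling.** Latent columns are standardized to the
  spec's SDs exactly. The generator defines the study conditions; recovery
  tests should measure the pipeline's error, not the Monte-Carlo error of
  the latent draw (at n = 120 the sample SD of a latent would otherwise
  wander by ~6.5%).
* **Calibrated three-factor preset.** `three_factor_spec()` activates only
  mouth curvature, eye size and brow height, with latent SDs calibrated
  against the eigenvalues of the Gram matrix of the similarity-projected
  displacement fields so the population shape covariance has component SDs
  in ratio 3:2:1. The fields are not mutually orthogonal (projecting out
  translation couples them), so calibrating each field's norm separately
  would miss the target ratio by ~15%.

What passing tests on this cohort do **not** show: robustness to
photographic nuisance (lighting gradients, pose, expression, occlusion),
to landmark schemes other than a fixed template, or to rating scales with
strong floor/ceiling usage. The cartoon textures are smooth by
construction; real photographs carry high-frequency detail that the
texture PCA would spread over many more components.

# Problem sizes and runtimes

The shipped tests and the acceptance script run at desk scale by choice:
cohorts of 120 (recovery) or 240 (full pipeline) ratees at 64 × 64 px,
cross-validation at 20 folds with 3–10 repeats, permutation tests at
10,000 repeats where a single p-value is reported and 300–2,000 where a
matrix of p-values is only masked. The full pipeline (cohort → two
appearance models → reliability → associations → 24 cross-validated traits
→ extreme faces → simulated validation) completes in about half a minute
on one CPU.

# Known limitations

* No appearance-model *search*: the model projects faces with known
  landmarks; it does not fit landmarks to new unannotated images.
* Shape and texture PCAs are kept separate (no combined third PCA); the
  regression operates on the concatenated standardized scores.
* The α schemes for incomplete designs are principled but not unique;
  judge panels with systematic (non-random) assignment would need a
  different treatment.
* Non-linear predictors (SVMs, neural networks) are out of scope by
  design; the linear model is the reference point.
* RGB images are supported by channel stacking, but all defaults and tests
  operate in grayscale.
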
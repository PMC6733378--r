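---
title: "Hip shape modelling with hipSSM: methods and design"
author: "hipSSM maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hip shape modelling with hipSSM: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipSSM)
```

## The problem

Hip morphology is a risk factor for osteoarthritis and osteoporotic
fracture, but single geometric indices (neck-shaft angle, neck width)
capture only fragments of it and are confounded by body size. A
statistical shape model (SSM) instead describes the whole proximal
femur contour: a set of ordered landmarks per image, aligned to remove
nuisance similarity transforms, and decomposed by PCA into orthogonal
modes of variation ("hip shape modes", HSMs). Each individual is then a
short vector of standardized mode scores, comparable across people and
— when a frozen reference model is used — across studies and time
points.

This vignette records the modelling choices, the synthetic-data
generator that stands in for managed-access clinical images, the
numerical conventions, and the limits of what the test suite
demonstrates.

## Alignment

Shapes are compared only after removing translation, size and rotation:

1. **Translation** — each configuration is centred on its centroid.
2. **Size** — each is scaled to unit *centroid size*
   $S(x) = \sqrt{\sum_j \lVert p_j - \bar p\rVert^2}$. The size measure
   is a convention; centroid size is the geometric-morphometrics
   standard, and scaling is removed fully (no partial-Procrustes
   option) because the scores are meant to be size-free.
3. **Rotation** — generalized Procrustes analysis: initialize the mean
   as the first normalized configuration, rotate every configuration
   onto the mean by the orthogonal Procrustes solution (SVD of the
   $2\times2$ cross-covariance with a sign correction on the smallest
   singular value, so reflections are never introduced), re-estimate
   the mean as the coordinate-wise average renormalized to unit size,
   and iterate.

Convergence is declared when the mean moves less than `tol` (default
$10^{-10}$, Euclidean norm) between iterations, with `maxIter = 100`;
on typical populations four or five iterations suffice. Non-convergence
is a warning plus a `converged = FALSE` flag, never an error, because a
near-converged alignment is still usable and the caller should decide.
After convergence one final rotation pass aligns all shapes to the
converged mean, so the stored configurations are optimally rotated to
the frame in which the model is built.

Mirroring (left vs right hips) is deliberately *not* automatic:
reflections are never allowed inside the alignment, and a caller who
has mixed sides must flip x coordinates explicitly (`mirrorX` in the
pipeline). Silent reflection handling can hide data-entry errors. The
detached acetabular-eyebrow points participate in alignment exactly
like femur points — the template is one rigid configuration.

## The shape model

PCA is performed on the aligned coordinate vectors: eigen-decomposition
of their sample covariance (divisor $n-1$), centred at the **arithmetic
mean of the aligned shapes**. That centring choice matters: it is what
makes training scores have *exactly* zero mean, and the eigenvalue
identity $\mathrm{Var}(s_m \sigma_m) = \lambda_m$ is what makes their
SDs exactly one after dividing by $\sigma_m = \sqrt{\lambda_m}$. (The
unit-size renormalized GPA mean differs from this arithmetic mean by a
vector of negligible but nonzero norm; centring there would leave
residual score means of that order.) The `gpa()` object reports its own
unit-size mean shape separately.

Conventions, all chosen for reproducibility of saved models:

- modes sorted by descending eigenvalue;
- deterministic sign: each eigenvector's largest-magnitude entry is
  positive (PCA signs are otherwise arbitrary and platform-dependent);
- modes with eigenvalues below $10^{-10}$ times the leading eigenvalue
  are dropped. Centring removes two directions exactly (the x and y
  translation sums), and unit-size scaling plus rotation quotienting
  leave two more near-zero directions; keeping them would produce
  0/0 scores. Variance fractions are computed against the total
  variance, so the retained fractions sum to 1 up to that negligible
  remainder — the "modes explain 100% of variance" contract holds to
  $10^{-8}$ comfortably.

`truncateModel()` keeps the leading modes (10 by default in the
pipeline, the conventional choice beyond which each mode carries under
about 1.5% of variance); fractions are not renormalized, so cumulative
variance explained is unchanged by truncation.

## Projection onto a frozen reference

`projectShapes()` scores new configurations against a saved model
without touching it: centre, scale to unit size, rotate onto the model
mean, subtract the mean, project onto the saved eigenvectors, divide by
the *reference* training SDs. No joint re-alignment is run — the
reference population's frame and scale conventions are the fixed
yardstick, which is the point of a reference model. Projected external
populations can and should show nonzero means and SDs below one when
they are more homogeneous than the reference; the tests construct
exactly such populations.

One numerical subtlety is documented rather than hidden: the unit-size
normalization is a nonlinear operation, so projecting a *reconstructed*
shape $\bar x + 2\sigma_m e_m$ (which does not have unit centroid size)
reproduces the score 2 only to about three decimal places, and the
renormalization leaks a small mean-direction component into the other
modes — order $10^{-3}$ SD on a 10-mode model, but potentially large in
SD units on near-zero-variance modes of an untruncated model. Scoring
the same reconstruction in the aligned coordinate frame
(`scoreTraining()` on its coordinate row) is exact to machine
precision, and projecting actual training shapes (which do have unit
size) reproduces training scores to better than $10^{-8}$.

## Reproducibility metrics

Point-to-point repeatability is computed on **raw pixel coordinates**,
not aligned ones, because placement error is reported in pixels against
a nominal 250 × 180 pixel image and alignment would rescale it. Per
image we report the mean landmark distance; across images, the mean and
the median, with the conventional "accurate if median ≤ 3 px" flag.

The ICC variant is fixed to two-way random effects, absolute agreement,
single measures,
$$\mathrm{ICC} = \frac{MS_S - MS_E}{MS_S + (k-1)MS_E + \tfrac{k}{n}(MS_R - MS_E)},$$
the conservative choice for test–retest of continuous scores (a
systematic offset between sessions counts against agreement). A
`type = "consistency"` switch exposes the consistency form for
sensitivity analyses. Per-mode ICCs between two sessions are computed
with both sessions scored against one fixed model, so the comparison
reflects marking error, not model drift; modes below 0.70 are flagged.

## Effective number of independent modes

After projection onto an external reference, previously independent
scores may correlate. The spectral summary of a score correlation
matrix $R$ uses Nyholt's estimator
$$V_{\mathrm{eff}} = 1 + (M-1)\Bigl(1 - \frac{\mathrm{Var}(\lambda)}{M}\Bigr),$$
with the eigenvalue sample variance taken with divisor $M-1$ — this is
the divisor convention of the published matSpD implementation, and with
it the two shipped 10 × 10 correlation matrices both yield 9.6 (to one
decimal), i.e. a 4% loss of independence to the nearest percent. Li and
Ji's $M_{\mathrm{eff}} = \sum_i [\mathbf 1(\lambda_i \ge 1) +
(\lambda_i - \lfloor \lambda_i \rfloor)]$ is reported alongside; on
these matrices it gives 9.0, so the two estimators are deliberately not
interchangeable. Correlations are used as given (signed), not absolute;
values are kept at full precision internally and rounded to one decimal
only for display.

## The synthetic-data generator

No public femur-landmark dataset exists at this markup, so the
generator is first-class, tested code. Its design:

- **Base shape** — a parametric schematic proximal femur (head arc,
  neck, greater/lesser trochanter bumps, shaft segments, plus the
  detached two-segment acetabular eyebrow) in a nominal 250 × 180 pixel
  frame, in the raster convention (x rightward, y downward). It is
  drawn from arcs and line segments, not traced from any image. The
  default 58-point markup labels 13 key anatomical points and excludes
  indices {0, 1, 44, 45, 57}, giving the standard 53-point model; other
  even counts ≥ 12 resample the outline by arc length.
- **True modes** — smooth low-frequency random displacement fields
  (truncated Fourier series in the point index), projected out of the
  four-dimensional similarity tangent space at the base shape
  (translations, scaling, infinitesimal rotation) and Gram–Schmidt
  orthonormalized. The similarity projection is essential: without it,
  part of each planted mode would be absorbed by Procrustes alignment
  and mode recovery would be systematically biased. Smoothness mimics
  the fact that PCA modes of real outlines are anatomically smooth.
- **Population** — image $i$ is
  $T_i(\mathrm{base} + \sum_m s_{im}\sigma_m e_m) + \varepsilon$ with
  standard-normal true scores, a similarity nuisance transform drawn
  uniformly from configurable ranges (defaults: rotation ±15°, scale
  0.9–1.1, translation ±20 px — plausible DXA positioning variation),
  and i.i.d. normal marking noise per coordinate (default 1 px,
  consistent with reported manual placement errors of 1–2 px). An
  optional anisotropic x-scale emulates scanner pixel-spacing
  differences qualitatively. Everything is reproducible from an integer
  seed.

Default ground-truth settings used throughout the tests: three modes
with score SDs (10, 5, 2) px on a base of centroid size ≈ 520 px, i.e.
dominant modes of a few percent of size, well inside the linear regime
of Procrustes shape space.

What the generator does *not* emulate: correlated (structured)
marking error along the contour, observer drift between sessions,
genuine nonlinear shape variation, scanner-specific aspect-ratio
physics beyond a global x-scale, and any demographic covariate
structure. Tests passing on synthetic data therefore validate the
algebra and the pipeline's contracts, not claims about real DXA
populations; the real-data operating characteristics (85% variance in
ten modes, specific ICC levels, 1.2–1.8 px repeatability) depend on
managed-access images and are represented here only by structural
property checks at comparable noise scales.

## Problem sizes and verification points

The test suite and the acceptance script run entirely on generated
data at these sizes, chosen so each check has clear statistical margin:

- standardization and projection self-consistency: n = 500 images,
  1 px noise (contracts hold to $10^{-8}$, observed ~$10^{-13}$);
- planted-subspace recovery: n = 500, 0.1 px noise — largest principal
  angle below 5°, per-mode score correlation above 0.95. At n ≈ 100–200
  the third mode's eigenvector is not yet this stable (angles of
  10–15°), which is a sampling property of PCA, not an implementation
  artifact; the unit tests assert the looser bound at small n and the
  sharp bound at the stated size;
- Monte-Carlo oracles: $10^5$ draws for correlation recovery, 100
  images × 58 points for the Rayleigh repeatability closed form
  (two sessions of i.i.d. $N(0,\sigma^2)$ noise give point distances
  Rayleigh-distributed with scale $\sigma\sqrt2$, hence mean
  $\sigma\sqrt\pi$), asserted within four standard errors.

## Known limitations

- 2D landmarks only; no 3D, no sliding semi-landmarks, no thin-plate
  spline warping.
- Full Procrustes only (size always removed); raw eigenvalue
  magnitudes depend on the unit-size convention, though standardized
  scores do not.
- Projection assumes the reference and target share the landmark
  template exactly; there is no landmark matching or resampling across
  templates.
- The exclusion ledger is accounting, not quality control: image
  quality decisions are the caller's.
- ICC assumes a complete two-way layout; unbalanced designs are out of
  scope.
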
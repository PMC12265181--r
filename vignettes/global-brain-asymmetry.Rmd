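---
title: "Measuring global brain asymmetry: slice-wise GMSD and a MIMIC model"
author: "hemisym"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring global brain asymmetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemisym)
```

## The model and its assumptions

The package quantifies bilateral asymmetry of a skull-stripped brain
volume in two stages.

**Stage 1 — per-slice asymmetry.** A 2D slice is asymmetric to the extent
that it differs from its own mirror image once optimally aligned. The
dissimilarity measure is the Gradient Magnitude Similarity Deviation
(GMSD). For an image $A$, the gradient magnitude is
$G_A(i,j) = \sqrt{G_x^2 + G_y^2}$, the horizontal/vertical responses of a
3×3 derivative kernel pair. Two images are compared pixel-wise through

$$\mathrm{GMS}(i,j) = \frac{2\,G_A G_B + C}{G_A^2 + G_B^2 + C},$$

which lies in $(0, 1]$ with equality exactly where the gradient
magnitudes agree, and pooled by the population standard deviation
(divisor $N$, the pixel count):
$\mathrm{GMSD} = \mathrm{sd}(\mathrm{GMS})$, with
$\mathrm{GMSM} = \mathrm{mean}(\mathrm{GMS})$. Identical images give
GMSD $= 0$; larger values mean greater dissimilarity, and since the map
is bounded in $(0,1]$, GMSD is bounded by $0.5$.

The symmetry axis of a slice is located by exhaustive search
(`findSymmetryAxis()`): the slice is recentered on its intensity
centroid (integer shift), the center is perturbed over the full integer
grid $\{-2,\dots,2\}^2$, each candidate is rotated on a signed grid of
0.5° steps up to ±5°, mirrored across its central vertical axis, and
scored with GMSD. The minimal score over all
$25 \times 21 = 525$ candidates is the slice's **asymmetry index**; the
winning rotation/offset define the axis. Ties break deterministically:
smallest $|\text{angle}|$, then smallest $|dx|+|dy|$, then enumeration
order — reproducibility over arbitrary choice.

**Stage 2 — integration.** Eleven slice indices per subject (diagonal
`dg`; axial 68, 78, 88, 98, 108; coronal 84, 94, 104, 114, 124 — central
slices spaced 10 voxels apart, where the axis is least ambiguous) are
treated as indicators of a latent *Global Asymmetry* factor in a MIMIC
(Multiple Indicators Multiple Causes) structural equation model,

$$y_k = \lambda_k\,\mathrm{GA} + \varepsilon_k, \qquad
  \mathrm{GA} = \gamma_{\mathrm{ses}}\,x_{\mathrm{ses}}
   + \gamma_{\mathrm{age}}\,x_{\mathrm{age}}
   + \gamma_{\mathrm{sex}}\,x_{\mathrm{sex}} + \zeta,$$

with residual covariances between four adjacent-slice pairs
(`c94~~c104`, `c104~~c114`, `c114~~c124`, `a68~~a78`) that share local
anatomy beyond the global factor. Estimation is maximum likelihood on
the sample covariance matrix $S$ of the $p = 14$ modeled variables,
minimizing
$F(\theta) = \log|\Sigma(\theta)| - \log|S|
 + \mathrm{tr}(S\,\Sigma(\theta)^{-1}) - p$.
ML rests on the usual multinormality assumption; sex and SES are
discrete, so the normal theory is an approximation whose practical
adequacy the parameter-recovery simulations check directly.

## Conventions the results depend on

Choices the estimator and index definitions leave open are fixed as
follows (all configurable where noted):

* **Gradient kernel**: Prewitt pair normalized to `(1, 0, -1)/3` rows, so
  a unit step responds with the step height; `sobel` and `scharr`
  available. **Padding** is symmetric (edge-replicating), which makes the
  output the size of the input and makes mirroring commute with the
  gradient magnitude — the property the axis search exploits.
* **Stability constant**: `c = 170` quoted on a 0–255 intensity scale and
  rescaled by `(max intensity / 255)^2`, so PNG slices stored in 0–1
  behave identically. Within one axis search the constant is fixed once
  from the recentered slice, so all candidates are scored on the same
  scale. No downsampling by default (it would blur the axis geometry); a
  2× prefiltered decimation is available as an option.
* **Pooling region**: all pixels by default (the map is identically 1 on
  the empty background of a pair of skull-stripped slices); an optional
  dilated foreground mask restricts pooling to tissue.
* **Rotation**: bilinear interpolation about the canvas center, zero
  fill. **Recentering** uses nearest-integer shifts; sub-pixel residuals
  are deliberately delegated to the ±2 px candidate grid.
* **Axis reporting**: the result records the aligning rotation and offset;
  `alignToAxis()` reproduces the aligned image whose central vertical
  column is the axis (the overlay in the CLI draws it there rather than
  inverse-mapping into the original frame).
* **Volume orientation**: dim 1 = left–right, dim 2 =
  anterior–posterior, dim 3 = superior–inferior; slice indices are
  0-based to match the indicator names. Extracted slices always carry
  left–right along image *columns*, so `mirrorImage()` flips hemispheres
  in every plane. The **diagonal slice** is a package convention: the
  plane through the volume center obtained by pitching the axial plane
  about the left–right axis (default 45°), resampled bilinearly — the
  study's exact oblique geometry is not recoverable from its description.
* **χ² multiplier**: $(n-1)\,F_{\min}$ (Wishart convention). The
  **exogenous block** $\Phi$ (predictor variances/covariances, 6 moments
  for 3 predictors) is fitted exactly at its sample values and counted
  among the parameters, which yields the full model's 70 degrees of
  freedom ($105 - 29 - 6$) and the CFA's 40 ($66 - 26$).
* **Baseline model** for CFI/TLI: all modeled variables uncorrelated,
  indicator variances fitted exactly, the exogenous block kept exactly
  fitted — consistent with the convention above.
* **Identification**: first loading fixed to 1 by default;
  `fix_latent_variance` is available, and the standardized solution is
  invariant to the choice (checked to 1e−6 in the tests).
* **Codings**: sex female = 0 / male = 1; SES is the raw Hollingshead
  score treated as numeric; age in years. Missing covariates are handled
  by listwise deletion.

## Numerical choices

* $F$ is minimized by `nlminb` with an analytic gradient
  ($\partial F/\partial\theta_j =
  \mathrm{tr}[(\Sigma^{-1} - \Sigma^{-1} S \Sigma^{-1})\,
  \partial\Sigma/\partial\theta_j]$), from a deterministic start (first
  principal axis of the indicator covariance for loadings, half the
  indicator variances for residuals, zero paths). No random restarts, so
  fits are bit-reproducible.
* The optimization runs on the **correlation-scaled** covariance
  ($D^{-1/2} S D^{-1/2}$): $F$ and χ² are invariant to diagonal
  rescaling, and asymmetry indices have variances around $10^{-4}$,
  which makes the raw-scale problem ill-conditioned. Estimates, standard
  errors and expected-parameter changes are mapped back to the raw
  metric through the induced diagonal reparameterization.
* Convergence is declared on the gradient norm at the optimum (with one
  deterministic restart), not on the optimizer's status code alone;
  non-convergence is flagged on the fit object and warned about, never
  silent. Negative variance estimates (Heywood cases) raise a flag.
* Standard errors come from the inverse expected information,
  $\mathrm{acov}(\hat\theta) = \tfrac{2}{n-1} E^{-1}$ with
  $E_{jk} = \mathrm{tr}(\Sigma^{-1}\Delta_j\Sigma^{-1}\Delta_k)$.
  Modification indices are univariate score tests with the free
  parameters partialed out; entries with numerically singular partialed
  information are returned as `NA`, not fabricated.
* The RMSEA 90% CI inverts the noncentral χ² distribution in the
  noncentrality parameter by monotone root-finding (tolerance 1e−8);
  the close-fit probability uses
  $\mathrm{ncp} = 0.05^2\,df\,(n-1)$. SRMR is the root mean squared
  standardized covariance residual over the $p(p+1)/2$ unique elements.
* Degenerate inputs fail loudly: all-zero images have no centroid,
  all-zero slices abort a subject's profile, non-positive-definite
  sample covariances are rejected before optimization, and
  over-parameterized specifications are caught by the df arithmetic
  (e.g. a 2-indicator one-factor model, which has more parameters than
  moments under any supported identification).

## What the synthetic generators emulate — and what they do not

`makePhantom()` builds a deliberately minimal brain-like slice: an
elliptical base with a soft edge, symmetric pairs of Gaussian blobs
(which break rotational symmetry, making the axis identifiable), an
optional one-sided blob of controlled amplitude, then rotation,
translation, and Gaussian / salt-and-pepper / speckle noise — the
distortion families relevant to MRI. Background intensities are exactly
zero, as in skull-stripped data. With zero amplitude, zero angle, zero
offset and no noise the image is *exactly* mirror-symmetric, giving the
tests a bit-level ground truth. The phantoms have no anatomical realism:
no cortical folding, no intensity inhomogeneity, no partial-volume
effects. Passing the recovery tests therefore shows the *algorithm*
(centroid, grid search, GMSD scoring) is correct and noise-tolerant at
the stated levels; it does not certify performance on real anatomy.

`simulateCohort()` draws cohorts from the generating MIMIC model in the
standardized metric: loadings default to the 0.64–0.87 profile over the
eleven indicators, paths to (ses −0.22, age 0.57, sex 0.40), and the
four adjacent-slice residual covariances to 0.10 — a value chosen once
as a plausible magnitude for shared local anatomy, since only its
existence, not its size, is prescribed. Predictors are drawn
independently: SES categorical on 1–4 with probabilities
25.8/34.8/22/17.4%, age normal(69, 12) truncated to [33, 94], sex
Bernoulli(0.28) — convenience emulations of the study composition, not
claims about the real marginals (in particular, real SES, age and sex
are correlated; here they are not). `populationMoments()` emits the
exact implied covariance for zero-discrepancy tests. Both generators are
pure functions of (parameters, seed).

## Problem sizes used in the validation suite

Unit tests run the axis search on 40–100 px phantoms with coarse grids
and the full 176×208 geometry where the claim requires it; the oracle
comparisons use 100 random 16×16 pairs (GMSD, tolerance 1e−10 relative)
and seeded 4-indicator datasets (estimates vs a generic BFGS optimizer
of the same discrepancy, 1e−4). Axis recovery is checked over angles
{−4°, −2°, 0°, 2°, 4°} × offsets {0, ±2 px}, noise-free and at Gaussian
σ = 5% of the dynamic range. Parameter recovery uses 200 cohorts of
n = 2000 at the default generating values: 95% Wald-interval coverage
must lie in [90%, 99%] for every free parameter and the mean
standardized estimates within 0.02 of the generating values. The
misspecification and modification-index detection simulations use 5–25
replicates at n = 500–2000.

## Known limitations

* The angle grid is discrete; no sub-degree continuous refinement, and
  no 3D midsagittal-plane fit — the axis is estimated independently per
  slice.
* GMSD compares gradient structure; two slices with mirrored geometry
  but globally rescaled intensities score as similar.
* ML assumes multinormal indicators; robust/weighted estimators, ordinal
  SEM, FIML for missing data, and multi-group invariance are out of
  scope.
* The diagonal-slice geometry is a documented convention, not a
  reconstruction of the study's oblique plane; cohort-level indices are
  comparable within a fixed configuration only.
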
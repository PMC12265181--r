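# hemisym

Global brain asymmetry from structural MRI, in two stages:

1. **Per-slice asymmetry via gradient magnitude similarity.** For a 2D
   slice *A* the gradient magnitude is
   `G_A(i,j) = sqrt(Gx(i,j)^2 + Gy(i,j)^2)` (3×3 Prewitt pair by default).
   Two images are compared through the per-pixel similarity map
   `GMS(i,j) = (2 G_A G_B + C) / (G_A^2 + G_B^2 + C)`, pooled by its
   population standard deviation, the **G**radient **M**agnitude
   **S**imilarity **D**eviation: `GMSD = sd(GMS)`; identical images give
   GMSD = 0. The symmetry axis of a slice is found by recentering the
   slice on its intensity centroid, perturbing the center by up to ±2 px,
   rotating in 0.5° steps up to ±5°, and mirroring each candidate across
   its central vertical axis; the candidate minimizing
   `GMSD(candidate, mirror(candidate))` defines the axis, and that minimal
   GMSD is the slice's **asymmetry index**.
2. **A latent Global Asymmetry factor via a MIMIC model.** Eleven slice
   indices per subject (one diagonal `dg`, axial `a68`–`a108`, coronal
   `c84`–`c124`) measure a latent factor `GA` regressed on socioeconomic
   status (Hollingshead score), age and sex:
   `y_k = λ_k GA + ε_k`, `GA = γ_ses ses + γ_age age + γ_sex sex + ζ`,
   with residual covariances between adjacent slices
   (`c94~~c104`, `c104~~c114`, `c114~~c124`, `a68~~a78`). Estimation is
   maximum likelihood on the sample covariance matrix; the package
   reports χ² (`(n−1)·F_ML`), CFI, TLI, RMSEA with 90% CI and close-fit
   probability, SRMR, modification indices, and the standardized solution,
   with the conventional two-step procedure (CFA first, then the
   structural model).

Intended users: researchers quantifying hemispheric asymmetry from
preprocessed (Talairach-aligned, skull-stripped) volumes, and anyone who
needs a small, dependency-light, fully testable MIMIC/CFA engine with
synthetic generators for validation.

## Worked example

```r
library(hemisym)

## a brain-like phantom rotated 2 degrees, with a one-sided blob and noise
ph  <- makePhantom(angle = 2, asymmetry = 40,
                   noise = "gaussian", noiseLevel = 0.05, seed = 42)
findSymmetryAxis(ph$image)
#> SymmetryAxisResult: angle = -1.50 deg, offset = (+0, +1) px
#>   asymmetry index = 0.112455 (525 candidates evaluated)
```

The search undoes the injected +2° rotation (recovered −1.5°, within one
0.5° grid step — the asymmetric blob tugs the optimum slightly), and the
index 0.11 reflects the injected one-sided structure; the same phantom
with `asymmetry = 0` and no noise scores ≤ 1e−6.

```r
## a synthetic cohort drawn from the generating MIMIC model, then the
## two-step fit (measurement model first, structural model second)
coh  <- simulateCohort(2000, seed = 1)
spec <- mimicSpec(predictors = c("ses_z", "age_z", "sex_z"))
twoStepFit(spec, coh)
#> == Step 1: measurement model (CFA) ==
#> chisq = 28.210 (df = 40), p = 0.9191
#> CFI = 1.000  TLI = 1.001  SRMR = 0.006
#> RMSEA = 0.000  90% CI [0.000, 0.006]  p(RMSEA <= .05) = 1.000
#>
#> == Step 2: full MIMIC model ==
#> chisq = 59.819 (df = 70), p = 0.8021
#> ...
#> Standardized paths:
#>     param        std
#>  GA~ses_z -0.2331730
#>  GA~age_z  0.5821638
#>  GA~sex_z  0.3860380
```

The recovered standardized paths sit close to the generating values
(−0.22, 0.57, 0.40); the full model has 70 degrees of freedom
(`semDf(mimicSpec())`). For volumes, `profileSubject()` /
`profileCohort()` produce the indicator table and `runPipeline()` chains
everything into CSV/JSON/text artifacts.

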
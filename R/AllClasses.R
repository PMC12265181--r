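#' @import methods
NULL

#' Result of a GMSD comparison between two images
#'
#' Holds the Gradient Magnitude Similarity Deviation (the population
#' standard deviation of the per-pixel gradient-magnitude similarity map),
#' its mean (GMSM), and the map itself.
#'
#' @slot gmsd numeric scalar in \[0, 0.5\]; 0 means the gradient structure
#'   of the two images is identical, larger values mean more dissimilar.
#' @slot gmsm numeric scalar in (0, 1\]; mean of the similarity map.
#' @slot map numeric matrix of per-pixel similarities, each in (0, 1\].
#'
#' @seealso [gmsd()]
#' @export
setClass("GmsdResult",
  representation(gmsd = "numeric", gmsm = "numeric", map = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(object@gmsd) != 1L || !is.finite(object@gmsd) ||
        object@gmsd < 0 || object@gmsd > 0.5)
      msg <- c(msg, "'gmsd' must be a finite scalar in [0, 0.5]")
    if (length(object@gmsm) != 1L || !is.finite(object@gmsm) ||
        object@gmsm <= 0 || object@gmsm > 1 + 1e-12)
      msg <- c(msg, "'gmsm' must be a finite scalar in (0, 1]")
    if (length(msg)) msg else TRUE
  }
)

#' Symmetry axis of a 2D slice
#'
#' The optimal (rotation, center offset) found by the exhaustive candidate
#' search of [findSymmetryAxis()], together with the asymmetry index (the
#' minimal GMSD between the aligned slice and its mirror image).
#'
#' @slot angle numeric; signed rotation (degrees) applied to the recentered
#'   slice so that its central vertical axis is the symmetry axis.
#' @slot dx,dy integer; best center perturbation in pixels (columns, rows).
#' @slot index numeric; asymmetry index, the GMSD at the optimum, in
#'   \[0, 0.5\].
#' @slot nCandidates integer; number of (offset, angle) pairs evaluated.
#'
#' @seealso [findSymmetryAxis()]
#' @export
setClass("SymmetryAxisResult",
  representation(angle = "numeric", dx = "integer", dy = "integer",
                 index = "numeric", nCandidates = "integer"),
  validity = function(object) {
    msg <- character()
    if (!is.finite(object@index) || object@index < 0 || object@index > 0.5)
      msg <- c(msg, "'index' must lie in [0, 0.5]")
    if (object@nCandidates < 1L)
      msg <- c(msg, "'nCandidates' must be positive")
    if (length(msg)) msg else TRUE
  }
)

## canonical indicator order used throughout (diagonal, axials, coronals)
.INDICATORS <- c("dg", "a68", "a78", "a88", "a98", "a108",
                 "c84", "c94", "c104", "c114", "c124")

#' Per-subject profile of slice asymmetry indices
#'
#' Eleven named slice asymmetry indices for one subject: the diagonal slice
#' (`dg`), axial slices 68--108 (`a68`...`a108`) and coronal slices 84--124
#' (`c84`...`c124`), plus per-slice search diagnostics.
#'
#' @slot subjectID character scalar.
#' @slot indices named numeric vector of length 11, all in \[0, 0.5\].
#' @slot diagnostics data.frame with one row per slice (angle, dx, dy,
#'   candidates evaluated).
#'
#' @seealso [profileSubject()]
#' @export
setClass("AsymmetryProfile",
  representation(subjectID = "character", indices = "numeric",
                 diagnostics = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (length(object@indices) != 11L ||
        !identical(names(object@indices), .INDICATORS))
      msg <- c(msg, "'indices' must be the 11 named slice indices")
    if (anyNA(object@indices) || any(object@indices < 0) ||
        any(object@indices > 0.5))
      msg <- c(msg, "all indices must lie in [0, 0.5] with none missing")
    if (length(msg)) msg else TRUE
  }
)

#' Declarative MIMIC model specification
#'
#' Describes the Multiple Indicators Multiple Causes model: a single latent
#' factor measured by the named indicators, optionally regressed on observed
#' predictors, with selected pairs of indicator residuals allowed to covary.
#'
#' @slot indicators ordered character vector of indicator names.
#' @slot latent name of the latent factor.
#' @slot predictors character vector of predictor (cause) names; empty for a
#'   pure CFA.
#' @slot residualCov two-column character matrix of indicator pairs whose
#'   residuals covary.
#' @slot identification `"fix_first_loading"` (first loading = 1) or
#'   `"fix_latent_variance"` (latent disturbance variance = 1).
#' @slot structural logical; if `FALSE` the predictors are ignored and the
#'   measurement (CFA) model alone is fitted.
#'
#' @seealso [mimicSpec()], [fitMimic()]
#' @export
setClass("MimicSpec",
  representation(indicators = "character", latent = "character",
                 predictors = "character", residualCov = "matrix",
                 identification = "character", structural = "logical"),
  validity = function(object) {
    msg <- character()
    if (length(object@indicators) < 2L || anyDuplicated(object@indicators))
      msg <- c(msg, "need >= 2 distinct indicators")
    if (!object@identification %in%
        c("fix_first_loading", "fix_latent_variance"))
      msg <- c(msg, "unknown identification constraint")
    rc <- object@residualCov
    if (nrow(rc)) {
      if (!all(rc %in% object@indicators))
        msg <- c(msg, "residual covariance pairs must name indicators")
      key <- apply(rc, 1L, function(p) paste(sort(p), collapse = "~~"))
      if (anyDuplicated(key) || any(rc[, 1L] == rc[, 2L]))
        msg <- c(msg, "residual covariance pairs must be distinct pairs")
    }
    if (object@structural && length(object@predictors) == 0L)
      msg <- c(msg, "structural part requested but no predictors given")
    if (length(msg)) msg else TRUE
  }
)

#' Fitted MIMIC / CFA model
#'
#' Maximum-likelihood fit of a covariance-structure model: free parameter
#' estimates with standard errors, the full parameter matrices, the
#' model-implied covariance, the discrepancy function value and chi-square
#' test, plus convergence diagnostics.
#'
#' @slot spec the [MimicSpec-class] that was fitted.
#' @slot est named numeric vector of free parameter estimates.
#' @slot se named numeric vector of standard errors (expected information).
#' @slot vcov asymptotic covariance matrix of the free parameters.
#' @slot theta list of full parameter matrices: `lambda`, `gamma`, `psi`,
#'   `theta` (residual covariance matrix), `phi` (exogenous block, fitted
#'   exactly at its sample value), `varLatent`.
#' @slot sigma model-implied covariance matrix of all modeled variables.
#' @slot moments list with the sample moments used (`cov`, `means`, `n`,
#'   `names`).
#' @slot fmin value of the ML discrepancy at the minimum.
#' @slot chisq,df,pvalue chi-square test of exact fit (`(n-1) * fmin`).
#' @slot converged logical; optimizer convergence.
#' @slot nIter integer; optimizer iterations.
#' @slot heywood logical; `TRUE` when a variance estimate is negative.
#'
#' @seealso [fitMimic()], [fitIndices()], [standardizedSolution()]
#' @export
setClass("SemFit",
  representation(spec = "MimicSpec", est = "numeric", se = "numeric",
                 vcov = "matrix", theta = "list", sigma = "matrix",
                 moments = "list", fmin = "numeric", chisq = "numeric",
                 df = "integer", pvalue = "numeric", converged = "logical",
                 nIter = "integer", heywood = "logical"),
  validity = function(object) {
    msg <- character()
    if (object@fmin < -1e-8) msg <- c(msg, "'fmin' must be >= 0")
    if (object@df < 0L) msg <- c(msg, "'df' must be >= 0")
    if (length(msg)) msg else TRUE
  }
)
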
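## Symmetry-axis search for a 2D slice: centroid recentering, a small grid
## of integer center perturbations, a signed rotation grid, mirroring, and
## GMSD scoring. The candidate minimizing GMSD defines the symmetry axis
## (the central vertical axis of the aligned image); that minimal GMSD is
## the slice's asymmetry index.

#' Intensity-weighted centroid of a grayscale image
#'
#' `cx` is the intensity-weighted mean column index, `cy` the weighted mean
#' row index (1-based pixel coordinates). Translating the image content
#' translates the centroid by the same amount.
#'
#' @param img numeric matrix with non-negative intensities, total > 0.
#' @return named numeric vector `c(cx, cy)`.
#' @export
imageCentroid <- function(img) {
  .checkGray(img)
  tot <- sum(img)
  if (tot <= 0)
    stop("all-zero image: centroid undefined", call. = FALSE)
  cx <- sum(img * col(img)) / tot
  cy <- sum(img * row(img)) / tot
  c(cx = cx, cy = cy)
}

#' Translate an image by an integer pixel shift
#'
#' Content moves `dx` columns right and `dy` rows down; vacated pixels are
#' zero-filled and the canvas size is unchanged.
#'
#' @param img numeric matrix.
#' @param dx,dy integer shifts (columns, rows).
#' @return shifted matrix.
#' @export
translateImage <- function(img, dx, dy) {
  h <- nrow(img); w <- ncol(img)
  dx <- as.integer(round(dx)); dy <- as.integer(round(dy))
  out <- matrix(0, h, w)
  srcR <- seq_len(h) - dy
  srcC <- seq_len(w) - dx
  okR <- srcR >= 1L & srcR <= h
  okC <- srcC >= 1L & srcC <= w
  if (any(okR) && any(okC))
    out[which(okR), which(okC)] <- img[srcR[okR], srcC[okC], drop = FALSE]
  out
}

#' Recenter an image on its intensity centroid
#'
#' Shifts the image by the nearest-integer translation that moves the
#' centroid onto the geometric canvas center `((w+1)/2, (h+1)/2)`. Sub-pixel
#' residual centering is deliberately left to the candidate-offset grid of
#' the axis search.
#'
#' @param img numeric matrix, total intensity > 0.
#' @param clipFraction maximum tolerated fraction of total intensity pushed
#'   off the canvas by the shift before an error is raised.
#' @return recentered matrix (same canvas).
#' @export
recenterImage <- function(img, clipFraction = 0.1) {
  cen <- imageCentroid(img)
  h <- nrow(img); w <- ncol(img)
  dx <- round((w + 1) / 2 - cen["cx"])
  dy <- round((h + 1) / 2 - cen["cy"])
  out <- translateImage(img, dx, dy)
  lost <- 1 - sum(out) / sum(img)
  if (lost > clipFraction)
    stop(sprintf("recentering would clip %.1f%% of image intensity",
                 100 * lost), call. = FALSE)
  out
}

#' Candidate center offsets for the axis search
#'
#' All integer offsets `(dx, dy)` with `|dx| <= r` and `|dy| <= r`, in a
#' deterministic order: `(0, 0)` first, then row-major over the remaining
#' grid. `r = 2` (the default search) yields 25 candidates.
#'
#' @param radius non-negative integer perturbation radius in pixels.
#' @return integer matrix with columns `dx`, `dy`.
#' @export
candidateCenters <- function(radius = 2L) {
  radius <- as.integer(radius)
  if (radius < 0L) stop("'radius' must be >= 0", call. = FALSE)
  g <- expand.grid(dx = -radius:radius, dy = -radius:radius,
                   KEEP.OUT.ATTRS = FALSE)
  g <- as.matrix(g)
  zero <- which(g[, "dx"] == 0L & g[, "dy"] == 0L)
  rbind(g[zero, , drop = FALSE], g[-zero, , drop = FALSE])
}

#' Rotate an image about its geometric center
#'
#' Bilinear interpolation, zero fill outside the source canvas, canvas size
#' unchanged. A positive angle rotates content clockwise when the image is
#' viewed with row 1 at the top.
#'
#' @param img numeric matrix.
#' @param angle rotation in degrees.
#' @return rotated matrix.
#' @export
rotateImage <- function(img, angle) {
  if (angle == 0) return(img)
  h <- nrow(img); w <- ncol(img)
  th <- angle * pi / 180
  ct <- cos(th); st <- sin(th)
  xc <- (w + 1) / 2; yc <- (h + 1) / 2
  cc <- rep(seq_len(w) - xc, each = h)
  rr <- rep(seq_len(h) - yc, times = w)
  sx <- ct * cc + st * rr + xc   # inverse rotation: gather from source
  sy <- -st * cc + ct * rr + yc
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0;   fy <- sy - y0
  out <- numeric(h * w)
  ok <- x0 >= 1 & x0 + 1 <= w & y0 >= 1 & y0 + 1 <= h
  if (any(ok)) {
    x0k <- x0[ok]; y0k <- y0[ok]; fxk <- fx[ok]; fyk <- fy[ok]
    i00 <- (x0k - 1) * h + y0k
    out[ok] <- (1 - fxk) * ((1 - fyk) * img[i00] + fyk * img[i00 + 1]) +
      fxk * ((1 - fyk) * img[i00 + h] + fyk * img[i00 + h + 1])
  }
  matrix(out, h, w)
}

#' Mirror an image across its central vertical axis
#'
#' Reverses the column order; an exact involution.
#'
#' @param img numeric matrix.
#' @return mirrored matrix.
#' @export
mirrorImage <- function(img) img[, rev(seq_len(ncol(img))), drop = FALSE]

#' Configuration of the symmetry-axis search
#'
#' Defaults follow the search design used for brain slices: rotations in
#' 0.5 degree steps up to 5 degrees to either side, center perturbations up
#' to 2 pixels in every direction, Prewitt gradients, stability constant 170
#' (0--255 scale).
#'
#' @param maxRotation maximum |rotation| in degrees.
#' @param rotationStep rotation grid step in degrees (> 0).
#' @param recenterRadius integer center-perturbation radius in pixels.
#' @param operator,c,rescaleC,mask GMSD settings, see [gmsd()].
#' @return a validated list of class `"AxisSearchConfig"`.
#' @export
axisSearchConfig <- function(maxRotation = 5, rotationStep = 0.5,
                             recenterRadius = 2L,
                             operator = c("prewitt", "sobel", "scharr"),
                             c = 170, rescaleC = TRUE, mask = FALSE) {
  operator <- match.arg(operator)
  if (rotationStep <= 0) stop("'rotationStep' must be > 0", call. = FALSE)
  if (maxRotation < rotationStep)
    stop("'maxRotation' must be >= 'rotationStep'", call. = FALSE)
  if (recenterRadius < 0) stop("'recenterRadius' must be >= 0", call. = FALSE)
  structure(list(maxRotation = maxRotation, rotationStep = rotationStep,
                 recenterRadius = as.integer(recenterRadius),
                 operator = operator, c = c, rescaleC = rescaleC,
                 mask = mask),
            class = "AxisSearchConfig")
}

#' Angle grid of an axis search
#'
#' Signed multiples of the step from `-maxRotation` to `+maxRotation`
#' (2 * max/step + 1 angles; 21 for the defaults).
#'
#' @param config an [axisSearchConfig()].
#' @return numeric vector of angles in degrees.
#' @export
rotationGrid <- function(config) {
  k <- floor(config$maxRotation / config$rotationStep + 1e-9)
  seq(-k, k) * config$rotationStep
}

## score one aligned candidate: gmsd(image, mirror(image)). Under symmetric
## padding the gradient magnitude of the mirror is the mirrored magnitude,
## so the gradient map is computed once.
.mirrorScore <- function(img, operator, cEff, mask) {
  g <- gradientMagnitude(img, operator)
  gm <- mirrorImage(g)
  map <- gmsMap(g, gm, cEff)
  if (mask) {
    fg <- .dilate(img > 0 | mirrorImage(img) > 0, 1L)
    v <- map[fg]
    if (!length(v)) v <- as.vector(map)
  } else v <- as.vector(map)
  m <- mean(v)
  sqrt(mean((v - m)^2))
}

#' Find the symmetry axis of a 2D slice
#'
#' Recenters the slice on its intensity centroid, then exhaustively
#' evaluates every combination of integer center offset (within
#' `recenterRadius`) and rotation (on the signed `rotationStep` grid): each
#' candidate image is rotated, mirrored across its central vertical axis,
#' and scored with [gmsd()]. The candidate with the smallest GMSD (greatest
#' mirror similarity) wins; ties are broken by smallest `|angle|`, then
#' smallest `|dx| + |dy|`, then enumeration order. The winning GMSD is the
#' slice's asymmetry index.
#'
#' @param img numeric matrix (grayscale slice), total intensity > 0.
#' @param config an [axisSearchConfig()].
#' @return a [SymmetryAxisResult-class].
#' @examples
#' ph <- makePhantom(height = 64, width = 72, asymmetry = 0)
#' res <- findSymmetryAxis(ph$image, axisSearchConfig(maxRotation = 1))
#' asymmetryIndex(res)   # ~0 for an exactly mirror-symmetric phantom
#' @export
findSymmetryAxis <- function(img, config = axisSearchConfig()) {
  .checkGray(img)
  base <- recenterImage(img)
  offsets <- candidateCenters(config$recenterRadius)
  angles <- rotationGrid(config)
  cEff <- .effectiveC(config$c, base, base, config$rescaleC)
  nOff <- nrow(offsets); nAng <- length(angles)
  score <- matrix(NA_real_, nAng, nOff)
  for (o in seq_len(nOff)) {
    cand <- if (offsets[o, "dx"] == 0L && offsets[o, "dy"] == 0L) base
            else translateImage(base, offsets[o, "dx"], offsets[o, "dy"])
    for (a in seq_len(nAng))
      score[a, o] <- .mirrorScore(rotateImage(cand, angles[a]),
                                  config$operator, cEff, config$mask)
  }
  ord <- order(as.vector(score),
               abs(angles)[rep(seq_len(nAng), nOff)],
               (abs(offsets[, "dx"]) + abs(offsets[, "dy"]))[
                 rep(seq_len(nOff), each = nAng)],
               seq_len(nAng * nOff))
  best <- ord[1L]
  aI <- (best - 1L) %% nAng + 1L
  oI <- (best - 1L) %/% nAng + 1L
  new("SymmetryAxisResult",
      angle = angles[aI],
      dx = as.integer(offsets[oI, "dx"]), dy = as.integer(offsets[oI, "dy"]),
      index = score[aI, oI], nCandidates = as.integer(nAng * nOff))
}

#' @describeIn findSymmetryAxis rotation (degrees) of the best candidate.
#' @param x a `SymmetryAxisResult`.
#' @export
axisAngle <- function(x) x@angle

#' @describeIn findSymmetryAxis best center offset `c(dx, dy)` in pixels.
#' @export
axisOffset <- function(x) c(dx = x@dx, dy = x@dy)

#' @describeIn findSymmetryAxis the asymmetry index (minimal GMSD).
#' @export
asymmetryIndex <- function(x) x@index

#' @describeIn findSymmetryAxis number of candidates evaluated.
#' @export
candidatesEvaluated <- function(x) x@nCandidates

setMethod("show", "SymmetryAxisResult", function(object) {
  cat(sprintf(paste0("SymmetryAxisResult: angle = %+.2f deg, ",
                     "offset = (%+d, %+d) px\n  asymmetry index = %.6f ",
                     "(%d candidates evaluated)\n"),
              object@angle, object@dx, object@dy, object@index,
              object@nCandidates))
})

#' Align a slice to its symmetry axis
#'
#' Applies the recentering, center offset and rotation of an axis-search
#' result, so that the symmetry axis is the central vertical axis of the
#' returned image.
#'
#' @param img the original slice.
#' @param result a [SymmetryAxisResult-class] for that slice.
#' @return aligned image matrix.
#' @export
alignToAxis <- function(img, result) {
  base <- recenterImage(img)
  rotateImage(translateImage(base, result@dx, result@dy), result@angle)
}
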
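## Gradient Magnitude Similarity Deviation (GMSD) between two grayscale
## images. Images are plain numeric matrices: rows are image rows (y),
## columns are image columns (x), intensities finite and >= 0.

.checkGray <- function(img, arg = deparse(substitute(img))) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("'", arg, "' must be a numeric matrix", call. = FALSE)
  if (nrow(img) < 3L || ncol(img) < 3L)
    stop("'", arg, "' must be at least 3x3 (gradient kernels are 3x3)",
         call. = FALSE)
  if (!all(is.finite(img)))
    stop("'", arg, "' contains non-finite intensities", call. = FALSE)
  if (any(img < 0))
    stop("'", arg, "' contains negative intensities", call. = FALSE)
  invisible(img)
}

## 3x3 horizontal-derivative kernels; vertical partner is the transpose.
## Normalizations chosen so the response to a unit step is the step height.
.kernels <- list(
  prewitt = matrix(c(1, 0, -1, 1, 0, -1, 1, 0, -1), 3L, 3L, byrow = TRUE) / 3,
  sobel   = matrix(c(1, 0, -1, 2, 0, -2, 1, 0, -1), 3L, 3L, byrow = TRUE) / 4,
  scharr  = matrix(c(3, 0, -3, 10, 0, -10, 3, 0, -3), 3L, 3L, byrow = TRUE) / 16
)

## symmetric (edge-replicating) padding by one pixel
.padSym1 <- function(img) {
  h <- nrow(img); w <- ncol(img)
  img[c(1L, seq_len(h), h), c(1L, seq_len(w), w)]
}

## 3x3 cross-correlation with symmetric padding; output shape = input shape
.conv3 <- function(img, k) {
  h <- nrow(img); w <- ncol(img)
  p <- .padSym1(img)
  out <- matrix(0, h, w)
  for (a in 0:2) for (b in 0:2) {
    if (k[a + 1L, b + 1L] == 0) next
    out <- out + k[a + 1L, b + 1L] * p[a + seq_len(h), b + seq_len(w)]
  }
  out
}

#' Gradient magnitude map of a grayscale image
#'
#' Per-pixel magnitude `sqrt(Gx^2 + Gy^2)` of the horizontal and vertical
#' responses of a 3x3 derivative kernel pair, the local "intensity change
#' strength". Boundaries use symmetric (edge-replicating) padding, so the
#' output has the shape of the input and mirroring the image mirrors the map.
#'
#' The kernels are normalized so that an intensity step of height `s`
#' produces a response of `s` (Prewitt rows are `(1, 0, -1)/3`).
#'
#' @param img numeric matrix, at least 3x3, finite non-negative intensities.
#' @param operator `"prewitt"` (default), `"sobel"` or `"scharr"`.
#' @return numeric matrix of non-negative gradient magnitudes, same shape.
#' @examples
#' gradientMagnitude(matrix(c(0, 0, 100, 100), 4, 4))
#' @export
gradientMagnitude <- function(img, operator = c("prewitt", "sobel", "scharr")) {
  .checkGray(img)
  operator <- match.arg(operator)
  kx <- .kernels[[operator]]
  gx <- .conv3(img, kx)
  gy <- .conv3(img, t(kx))
  sqrt(gx * gx + gy * gy)
}

#' Gradient magnitude similarity map
#'
#' Per-pixel similarity of two gradient magnitude maps,
#' `(2 * gA * gB + c) / (gA^2 + gB^2 + c)`, bounded in (0, 1] with equality
#' exactly where the two magnitudes agree. The constant `c > 0` stabilizes
#' the ratio where both gradients vanish.
#'
#' @param gA,gB non-negative numeric matrices of the same shape.
#' @param c positive stability constant, on the (squared) scale of the
#'   gradient values.
#' @return numeric matrix of similarities in (0, 1].
#' @export
gmsMap <- function(gA, gB, c) {
  if (!identical(dim(gA), dim(gB)))
    stop("'gA' and 'gB' must have the same shape", call. = FALSE)
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0)
    stop("'c' must be a positive scalar", call. = FALSE)
  (2 * gA * gB + c) / (gA * gA + gB * gB + c)
}

## stability constant on the conventional 0-255 intensity scale, rescaled
## to the actual dynamic range of the pair (c has units of intensity^2)
.effectiveC <- function(c, imgA, imgB, rescaleC) {
  if (!rescaleC) return(c)
  r <- max(imgA, imgB)
  if (r <= 0) c else c * (r / 255)^2
}

## 3x3 binary dilation, n passes
.dilate <- function(m, n = 1L) {
  for (i in seq_len(n)) {
    p <- .padSym1(m)
    h <- nrow(m); w <- ncol(m)
    acc <- matrix(FALSE, h, w)
    for (a in 0:2) for (b in 0:2)
      acc <- acc | p[a + seq_len(h), b + seq_len(w)]
    m <- acc
  }
  m
}

## 2x2 mean prefilter + decimation by 2 (optional, as in the original
## quality-assessment use of the measure)
.downsample2 <- function(img) {
  h <- nrow(img) %/% 2L; w <- ncol(img) %/% 2L
  i <- 2L * seq_len(h); j <- 2L * seq_len(w)
  (img[i - 1L, j - 1L, drop = FALSE] + img[i - 1L, j, drop = FALSE] +
     img[i, j - 1L, drop = FALSE] + img[i, j, drop = FALSE]) / 4
}

#' Gradient Magnitude Similarity Deviation between two images
#'
#' Computes the GMS map of two same-shaped grayscale images and pools it by
#' its population standard deviation: `gmsd = sqrt(mean((GMS - GMSM)^2))`
#' with `GMSM = mean(GMS)` (divisor `N`, the number of pooled pixels).
#' Identical images give `gmsd = 0`, `gmsm = 1`; higher GMSD means greater
#' dissimilarity. Used here as the per-slice brain asymmetry score when `B`
#' is the mirror image of `A`.
#'
#' @param imgA,imgB numeric matrices of the same shape (finite, >= 0).
#' @param operator gradient kernel, see [gradientMagnitude()].
#' @param c stability constant, quoted on a 0--255 intensity scale.
#' @param rescaleC if `TRUE` (default) `c` is rescaled by
#'   `(max intensity / 255)^2` so images on other scales (e.g. PNG 0--1)
#'   behave identically.
#' @param mask if `TRUE`, pool only over the foreground (pixels where either
#'   image is positive, dilated by `maskDilate` passes of a 3x3 window);
#'   default `FALSE` pools over all pixels.
#' @param maskDilate integer, dilation passes for the foreground mask.
#' @param downsample if `TRUE`, both images are 2x2 mean-filtered and
#'   decimated by 2 before comparison; default `FALSE` (preserves slice
#'   geometry for the axis search).
#' @return a [GmsdResult-class] object.
#' @examples
#' a <- matrix(runif(64, 0, 255), 8, 8)
#' gmsdValue(gmsd(a, a))   # 0: an image is maximally similar to itself
#' @export
gmsd <- function(imgA, imgB, operator = c("prewitt", "sobel", "scharr"),
                 c = 170, rescaleC = TRUE, mask = FALSE, maskDilate = 1L,
                 downsample = FALSE) {
  .checkGray(imgA); .checkGray(imgB)
  if (!identical(dim(imgA), dim(imgB)))
    stop("'imgA' and 'imgB' must have the same shape", call. = FALSE)
  operator <- match.arg(operator)
  if (downsample) {
    imgA <- .downsample2(imgA)
    imgB <- .downsample2(imgB)
  }
  cEff <- .effectiveC(c, imgA, imgB, rescaleC)
  gA <- gradientMagnitude(imgA, operator)
  gB <- gradientMagnitude(imgB, operator)
  map <- gmsMap(gA, gB, cEff)
  keep <- if (mask) .dilate(imgA > 0 | imgB > 0, maskDilate) else TRUE
  v <- if (isTRUE(keep)) as.vector(map) else map[keep]
  if (!length(v)) stop("empty pooling region", call. = FALSE)
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  new("GmsdResult", gmsd = s, gmsm = m, map = map)
}

#' @describeIn gmsd the GMSD value of a result object.
#' @param x a `GmsdResult`.
#' @export
gmsdValue <- function(x) x@gmsd

#' @describeIn gmsd the GMSM (map mean) of a result object.
#' @export
gmsmValue <- function(x) x@gmsm

#' @describeIn gmsd the per-pixel GMS map of a result object.
#' @export
similarityMap <- function(x) x@map

setMethod("show", "GmsdResult", function(object) {
  cat(sprintf("GmsdResult: gmsd = %.6f, gmsm = %.6f (%d x %d map)\n",
              object@gmsd, object@gmsm, nrow(object@map), ncol(object@map)))
})
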
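## Synthetic 2D brain-like phantoms and 3D phantom volumes with controlled
## symmetry properties and noise, plus ground truth for assertions. The
## phantoms are deliberately minimal (ellipse + Gaussian blobs): enough
## structure to exercise centroid, rotation, mirroring and GMSD without
## anatomical realism.

## run expr with a local, restored RNG state
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## intensity noise models; images are clamped to >= 0 afterwards
.applyNoise <- function(img, noise, noiseLevel) {
  switch(noise,
    none = img,
    gaussian = pmax(img + stats::rnorm(length(img), 0,
                                       noiseLevel * diff(range(img))), 0),
    salt_pepper = {
      u <- stats::runif(length(img))
      hi <- max(img)
      img[u < noiseLevel / 2] <- 0
      img[u >= noiseLevel / 2 & u < noiseLevel] <- hi
      img
    },
    speckle = pmax(img * (1 + noiseLevel * stats::rnorm(length(img))), 0),
    stop("unknown noise model '", noise, "'", call. = FALSE))
}

#' Synthetic mirror-symmetric brain phantom with controlled asymmetry
#'
#' Builds an elliptical base with symmetric pairs of Gaussian blobs, exactly
#' mirror-symmetric about the central vertical canvas axis, then (in order)
#' injects a one-sided blob of the requested amplitude, rotates by
#' `angle`, translates by `offset`, and adds noise. With
#' `asymmetry = 0, angle = 0, offset = c(0, 0), noise = "none"` the emitted
#' image satisfies `mirrorImage(img) == img` exactly.
#'
#' @param height,width canvas size in pixels (default 176 x 208).
#' @param baseIntensity intensity of the elliptical base (0--255 scale).
#' @param blobs data.frame of symmetric blob pairs with columns `dx`
#'   (column distance from the canvas center, mirrored to both sides), `y`
#'   (row as a fraction of height), `amp`, `sigma` (pixels); `NULL` uses a
#'   default three-pair layout that breaks rotational symmetry.
#' @param asymmetry amplitude (>= 0) of the one-sided blob.
#' @param asymmetryAt `c(dxFraction, yFraction)` position of the one-sided
#'   blob (right hemisphere), relative to canvas center / height.
#' @param angle true in-plane rotation (degrees) applied to the phantom.
#' @param offset integer `c(dx, dy)` translation applied after rotation.
#' @param noise `"none"`, `"gaussian"`, `"salt_pepper"` or `"speckle"`.
#' @param noiseLevel Gaussian/speckle sigma as a fraction of the dynamic
#'   range, or the salt-and-pepper corruption probability.
#' @param seed integer seed; the generator is a pure function of
#'   (parameters, seed).
#' @return list with `image` (matrix) and `truth` (list: `angle`, `offset`,
#'   `asymmetry`).
#' @examples
#' ph <- makePhantom(height = 64, width = 72, asymmetry = 40, angle = 2)
#' ph$truth
#' @export
makePhantom <- function(height = 176L, width = 208L, baseIntensity = 100,
                        blobs = NULL, asymmetry = 0,
                        asymmetryAt = c(0.22, 0.35), angle = 0,
                        offset = c(0L, 0L), noise = c("none", "gaussian",
                                                      "salt_pepper",
                                                      "speckle"),
                        noiseLevel = 0.05, seed = NULL) {
  noise <- match.arg(noise)
  if (asymmetry < 0) stop("'asymmetry' must be >= 0", call. = FALSE)
  h <- as.integer(height); w <- as.integer(width)
  if (is.null(blobs))
    blobs <- data.frame(dx = c(0.25, 0.12, 0.30) * w,
                        y = c(0.30, 0.55, 0.70),
                        amp = c(80, 90, 60),
                        sigma = c(0.035, 0.045, 0.03) * min(h, w))
  xc <- (w + 1) / 2; yc <- (h + 1) / 2
  X <- matrix(rep(seq_len(w) - xc, each = h), h, w)   # signed column offset
  Y <- matrix(rep(seq_len(h), times = w), h, w)
  ## elliptical base with a soft edge
  a <- 0.42 * w; b <- 0.40 * h
  r2 <- (X / a)^2 + ((Y - yc) / b)^2
  img <- baseIntensity * pmin(pmax((1.05 - r2) / 0.1, 0), 1)
  ## symmetric blob pairs: |X| makes each pair exactly mirror-symmetric
  for (k in seq_len(nrow(blobs))) {
    d2 <- (abs(X) - blobs$dx[k])^2 + (Y - blobs$y[k] * h)^2
    img <- img + blobs$amp[k] * exp(-d2 / (2 * blobs$sigma[k]^2))
  }
  if (asymmetry > 0) {
    dxa <- asymmetryAt[1] * w; ya <- asymmetryAt[2] * h
    sig <- 0.04 * min(h, w)
    d2 <- (X - dxa)^2 + (Y - ya)^2
    if (dxa + xc < 1 || dxa + xc > w || ya < 1 || ya > h)
      stop("one-sided blob lies outside the canvas", call. = FALSE)
    img <- img + asymmetry * exp(-d2 / (2 * sig^2))
  }
  ## skull-stripped images have an exactly-zero background; truncate the
  ## negligible Gaussian tails so the phantom does too
  img[img < 1e-6] <- 0
  if (angle != 0) img <- rotateImage(img, angle)
  if (any(offset != 0)) img <- translateImage(img, offset[1], offset[2])
  img <- .withSeed(seed, .applyNoise(img, noise, noiseLevel))
  list(image = img,
       truth = list(angle = angle, offset = as.integer(offset),
                    asymmetry = asymmetry))
}

#' Synthetic 3D phantom volume with per-slice ground truth
#'
#' Stacks axial 2D phantoms into a volume of the stated dimensions
#' (left-right, anterior-posterior, superior-inferior); the per-slice
#' asymmetry amplitude is controlled so that named axial indices hit
#' phantoms with known properties. Coronal and diagonal resections of a
#' symmetric stack are themselves mirror-symmetric.
#'
#' @param dims integer triple, default `c(176, 208, 176)`.
#' @param sliceAsymmetry either a single amplitude for every slice, or a
#'   function of the 0-based axial index returning the amplitude.
#' @param noise,noiseLevel,seed as in [makePhantom()]; the seed is advanced
#'   per slice deterministically.
#' @param ... further arguments passed to [makePhantom()].
#' @return list with `volume` (3D array) and `truth` (data.frame of slice
#'   index and amplitude).
#' @export
makePhantomVolume <- function(dims = c(176L, 208L, 176L),
                              sliceAsymmetry = 0, noise = "none",
                              noiseLevel = 0.05, seed = NULL, ...) {
  dims <- as.integer(dims)
  if (length(dims) != 3L) stop("'dims' must have length 3", call. = FALSE)
  ampAt <- if (is.function(sliceAsymmetry)) sliceAsymmetry
           else function(k) sliceAsymmetry
  vol <- array(0, dims)
  amps <- numeric(dims[3L])
  for (k in seq_len(dims[3L])) {
    amps[k] <- ampAt(k - 1L)
    ph <- makePhantom(height = dims[2L], width = dims[1L],
                      asymmetry = amps[k], noise = noise,
                      noiseLevel = noiseLevel,
                      seed = if (is.null(seed)) NULL else seed + k, ...)
    ## image rows = anterior-posterior, columns = left-right
    vol[, , k] <- t(ph$image)
  }
  list(volume = vol,
       truth = data.frame(slice = seq_len(dims[3L]) - 1L, asymmetry = amps))
}
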
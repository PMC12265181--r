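test_that("intensity centroid is the weighted mean position", {
  img <- matrix(0, 8, 12)
  img[4, 10] <- 5
  expect_equal(imageCentroid(img), c(cx = 10, cy = 4))

  img <- matrix(0, 3, 5)
  img[2, 1] <- 1; img[2, 5] <- 3
  expect_equal(unname(imageCentroid(img)["cx"]), (1 * 1 + 5 * 3) / 4)

  # uniform rectangle: geometric center
  img <- matrix(0, 10, 10)
  img[3:6, 5:8] <- 2
  expect_equal(imageCentroid(img), c(cx = 6.5, cy = 4.5))

  expect_error(imageCentroid(matrix(0, 5, 5)), "all-zero")
})

test_that("centroid shifts exactly with integer translations", {
  set.seed(5)
  img <- matrix(0, 30, 30)
  img[10:18, 12:20] <- matrix(runif(81, 1, 10), 9, 9)
  c0 <- imageCentroid(img)
  c1 <- imageCentroid(translateImage(img, 3, -2))
  expect_equal(c1, c0 + c(cx = 3, cy = -2))
})

test_that("recentering moves the centroid to the canvas center", {
  # point mass 5 px right of center lands at the center
  img <- matrix(0, 21, 21)
  img[11, 16] <- 1
  out <- recenterImage(img)
  expect_equal(which(out > 0, arr.ind = TRUE)[1, ],
               c(row = 11L, col = 11L))

  # already centered: identity; and one application is a fixed point
  ph <- makePhantom(height = 40, width = 44)$image
  r1 <- recenterImage(ph)
  expect_equal(recenterImage(r1), r1)

  # recentering that pushes outlying content off the canvas is an error
  img <- matrix(0, 21, 21)
  img[1:3, 1:3] <- 1       # centroid pulled to the top-left corner
  img[20, 20] <- 1         # this pixel falls off after the shift
  expect_error(recenterImage(img, clipFraction = 0), "clip")
})

test_that("candidate center grid is complete and deterministically ordered", {
  expect_equal(candidateCenters(0), cbind(dx = 0L, dy = 0L))
  expect_equal(nrow(candidateCenters(1)), 9L)
  g2 <- candidateCenters(2)
  expect_equal(nrow(g2), 25L)
  expect_equal(unname(g2[1, ]), c(0L, 0L))
  for (pt in list(c(2, 2), c(-2, -2), c(2, -2), c(-2, 2)))
    expect_true(any(g2[, "dx"] == pt[1] & g2[, "dy"] == pt[2]))
  expect_error(candidateCenters(-1), ">= 0")
})

test_that("rotation is exact at zero, invertible on the interior", {
  ph <- makePhantom(height = 60, width = 64)$image
  expect_identical(rotateImage(ph, 0), ph)

  rt <- rotateImage(rotateImage(ph, 3), -3)
  interior <- cbind(rep(15:45, each = 31), rep(20:50, times = 31))
  expect_lt(mean(abs(rt[interior] - ph[interior])), 1.0)

  # a 90-degree-symmetric pattern still changes under a 0.5-deg rotation
  sym <- matrix(0, 41, 41)
  sym[15:27, 15:27] <- 50
  expect_false(identical(rotateImage(sym, 0.5), sym))
})

test_that("mirroring reflects columns and is an exact involution", {
  img <- matrix(seq_len(12), 3, 4)
  expect_identical(mirrorImage(mirrorImage(img)), img)
  pt <- matrix(0, 3, 7); pt[2, 1] <- 9
  expect_equal(which(mirrorImage(pt) > 0, arr.ind = TRUE)[1, "col"],
               c(col = 7L))
  ph <- makePhantom(height = 30, width = 30)$image   # symmetric phantom
  expect_identical(mirrorImage(ph), ph)
})

test_that("axis search config validates and sizes its grids", {
  cfg <- axisSearchConfig()
  expect_equal(length(rotationGrid(cfg)), 21L)   # 2 * (5 / 0.5) + 1
  expect_equal(rotationGrid(axisSearchConfig(2, 1)), c(-2, -1, 0, 1, 2))
  expect_error(axisSearchConfig(rotationStep = 0), "rotationStep")
  expect_error(axisSearchConfig(maxRotation = 0.2, rotationStep = 0.5),
               "maxRotation")
  expect_error(axisSearchConfig(recenterRadius = -1), "recenterRadius")
})

test_that("a mirror-symmetric phantom yields a zero axis", {
  ph <- makePhantom(height = 80, width = 88)
  res <- findSymmetryAxis(ph$image, coarseConfig())
  expect_equal(axisAngle(res), 0)
  expect_equal(unname(axisOffset(res)), c(0L, 0L))
  expect_lt(asymmetryIndex(res), 1e-6)
  expect_equal(candidatesEvaluated(res), 9L * 5L)
})

test_that("a known rotation is recovered within one grid step", {
  ph <- makePhantom(height = 96, width = 104, angle = 2)
  res <- findSymmetryAxis(ph$image,
                          axisSearchConfig(3, 0.5, recenterRadius = 1L))
  expect_lte(abs(abs(axisAngle(res)) - 2), 0.5)
  expect_lt(asymmetryIndex(res), 0.02)
})

test_that("asymmetry index grows monotonically with injected amplitude", {
  idx <- vapply(c(0, 20, 40, 80, 160), function(a)
    asymmetryIndex(findSymmetryAxis(
      makePhantom(height = 80, width = 88, asymmetry = a)$image,
      axisSearchConfig(1, 0.5, recenterRadius = 1L))), numeric(1))
  expect_true(all(diff(idx) > 0))
})

test_that("the search result equals the naive double-loop optimum", {
  ph <- makePhantom(height = 48, width = 52, asymmetry = 30, angle = 1,
                    noise = "gaussian", noiseLevel = 0.03, seed = 3)
  res <- findSymmetryAxis(ph$image, axisSearchConfig(1, 0.5, 1L))
  ref <- naiveAxisSearch(ph$image, 1, 0.5, 1L)
  expect_equal(axisAngle(res), ref$angle)
  expect_equal(unname(axisOffset(res)), c(ref$dx, ref$dy))
  expect_equal(asymmetryIndex(res), ref$score, tolerance = 1e-12)
})

test_that("mirroring the input negates the recovered angle", {
  ph <- makePhantom(height = 80, width = 88, asymmetry = 25, angle = 1.5)
  cfg <- axisSearchConfig(3, 0.5, 1L)
  a1 <- axisAngle(findSymmetryAxis(ph$image, cfg))
  a2 <- axisAngle(findSymmetryAxis(mirrorImage(ph$image), cfg))
  expect_lte(abs(a1 + a2), 0.5)
})

test_that("aligning by the search result restores mirror symmetry", {
  ph <- makePhantom(height = 80, width = 88, angle = 2, offset = c(2, 1))
  res <- findSymmetryAxis(ph$image, axisSearchConfig(3, 0.5, 2L))
  al <- alignToAxis(ph$image, res)
  # rescore with the search's convention: constant fixed from the
  # recentered slice, not per candidate pair
  cEff <- 170 * (max(recenterImage(ph$image)) / 255)^2
  expect_equal(gmsdValue(gmsd(al, mirrorImage(al), c = cEff,
                              rescaleC = FALSE)),
               asymmetryIndex(res), tolerance = 1e-10)
  expect_lt(asymmetryIndex(res), 0.02)
})
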
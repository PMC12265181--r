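# All test volumes here are smaller than the 176x208x176 study geometry;
# extractSlice warns about that by design, so calls are wrapped.
exSlice <- function(...) suppressWarnings(extractSlice(...))

test_that("slice extraction follows the plane and index bookkeeping", {
  vol <- rampVolume(c(12L, 14L, 16L), axis = 3L)   # value = 0-based z
  expect_equal(exSlice(vol, "axial", 5L), matrix(5, 14, 12))
  expect_equal(dim(exSlice(vol, "axial", 0L)), c(14L, 12L))

  # coronal slice of the z-ramp equals the k-ramp image (naive loop)
  co <- exSlice(vol, "coronal", 7L)
  ref <- matrix(0, 16, 12)
  for (z in 1:16) for (x in 1:12) ref[z, x] <- vol[x, 8, z]
  expect_equal(co, ref)

  # left-right ramp: mirroring an axial slice reverses the ramp
  vlr <- rampVolume(c(12L, 14L, 16L), axis = 1L)
  ax <- exSlice(vlr, "axial", 3L)
  expect_equal(ax[1, ], 0:11)
  expect_equal(mirrorImage(ax)[1, ], 11:0)

  expect_error(exSlice(vol, "axial", 16L), "out of range")
  expect_error(exSlice(vol, "coronal", -1L), "out of range")
})

test_that("full-size volumes give the expected slice shapes silently", {
  vol <- array(1, c(176L, 208L, 176L))
  expect_no_warning(sl <- extractSlice(vol, "axial", 68L))
  expect_equal(dim(sl), c(208L, 176L))   # rows AP, columns LR
  expect_equal(dim(extractSlice(vol, "coronal", 84L)), c(176L, 176L))
  # trailing singleton channel is squeezed
  vol4 <- array(1, c(176L, 208L, 176L, 1L))
  expect_equal(dim(extractSlice(vol4, "axial", 68L)), c(208L, 176L))
})

test_that("the diagonal slice is a tilted central resection", {
  pv <- makePhantomVolume(dims = c(40L, 48L, 48L))
  dg <- exSlice(pv$volume, "diagonal")
  expect_equal(dim(dg), c(48L, 40L))
  expect_identical(mirrorImage(dg), dg)   # symmetric stack stays symmetric
  # pitch 0 degenerates to the central axial slice
  expect_equal(exSlice(pv$volume, "diagonal", pitch = 0),
               exSlice(pv$volume, "axial", (48L + 1L) %/% 2L - 0L))
})

test_that("profiles of symmetric stacks are zero and deterministic", {
  pv <- makePhantomVolume(dims = c(40L, 48L, 40L))
  cfg <- coarseConfig(1, 1, 1L)
  pr <- suppressWarnings(
    profileSubject(pv$volume, cfg, smallSliceSet(), subjectID = "ph1"))
  idx <- profileIndices(pr)
  expect_length(idx, 11L)
  expect_true(all(idx <= 1e-6))
  expect_equal(subjectID(pr), "ph1")
  pr2 <- suppressWarnings(
    profileSubject(pv$volume, cfg, smallSliceSet(), subjectID = "ph1"))
  expect_identical(profileIndices(pr2), idx)   # bit-identical rerun
})

test_that("asymmetry confined to superior slices shows up there only", {
  suppressWarnings(
    pv <- makePhantomVolume(dims = c(40L, 48L, 40L),
                            sliceAsymmetry = function(k)
                              if (k >= 22L) 60 else 0))
  cfg <- coarseConfig(1, 1, 0L)
  pr <- suppressWarnings(
    profileSubject(pv$volume, cfg, smallSliceSet()))
  idx <- profileIndices(pr)
  expect_gt(min(idx[c("a98", "a108")]), max(idx[c("a68", "a78")]))
})

test_that("degenerate slices abort the profile", {
  vol <- array(0, c(40L, 48L, 40L))
  vol[, , 25] <- 1   # only one nonzero slice
  expect_error(
    suppressWarnings(profileSubject(vol, coarseConfig(),
                                    smallSliceSet())),
    "degenerate")
})

test_that("cohort profiling filters, merges and keeps column order", {
  pv <- makePhantomVolume(dims = c(40L, 48L, 40L))$volume
  vols <- list(s1 = pv, s2 = pv, s3 = pv)
  cov <- data.frame(subject_id = c("s1", "s2", "s3"),
                    age = c(70, 65, 80), sex = c(0, 1, 0),
                    ses = c(2, NA, 3))
  tab <- suppressWarnings(suppressMessages(
    profileCohort(vols, cov, coarseConfig(1, 1, 0L), smallSliceSet())))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$subject_id, c("s1", "s3"))
  expect_equal(names(tab),
               c("subject_id", "dg", "a68", "a78", "a88", "a98", "a108",
                 "c84", "c94", "c104", "c114", "c124", "age", "sex",
                 "ses"))

  # duplicate ids are an error; unreadable volumes are skipped with a log
  expect_error(profileCohort(vols, rbind(cov, cov[1, ])), "duplicate")
  vols2 <- list(s1 = pv, s3 = "no/such/file.nii")
  tab2 <- suppressWarnings(suppressMessages(
    profileCohort(vols2, cov, coarseConfig(1, 1, 0L), smallSliceSet())))
  expect_equal(tab2$subject_id, "s1")

  # empty cohort: empty table plus a warning, not an error
  expect_warning(
    out <- suppressMessages(
      profileCohort(list(), cov, coarseConfig(), smallSliceSet())),
    "empty")
  expect_equal(nrow(out), 0L)
})

test_that("cohort composition percentages match the usual arithmetic", {
  cov <- data.frame(sex = c(rep(0, 95), rep(1, 37)),
                    ses = rep(1:4, c(34, 46, 29, 23)))
  comp <- cohortComposition(cov)
  expect_equal(comp$n, 132)
  expect_equal(comp$pctWomen, 72)
  expect_equal(comp$pctMen, 28)
  expect_equal(unname(comp$pctSES), c(25.8, 34.8, 22.0, 17.4))
})
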
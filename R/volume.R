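## Slice extraction from 3D volumes and per-subject / per-cohort profiling.
## Volume axis convention (configurable left-right axis documented in the
## vignette): dim 1 = left-right, dim 2 = anterior-posterior,
## dim 3 = superior-inferior. Extracted slices are oriented with the
## left-right axis along image columns, so mirroring columns flips
## hemispheres. Slice indices follow the 0-based numbering used to name the
## indicators (a68 ... c124).

.checkVolume <- function(vol) {
  if (length(dim(vol)) == 4L && dim(vol)[4L] == 1L)
    vol <- array(vol, dim(vol)[1:3])
  if (length(dim(vol)) != 3L)
    stop("volume must have 3 spatial dimensions (after channel squeeze)",
         call. = FALSE)
  if (!all(dim(vol) == c(176L, 208L, 176L)))
    warning("volume dimensions ", paste(dim(vol), collapse = "x"),
            " differ from the expected 176x208x176", call. = FALSE)
  vol
}

#' Extract a named 2D slice from a 3D volume
#'
#' Axial slices fix the superior-inferior coordinate (dim 3), coronal
#' slices fix the anterior-posterior coordinate (dim 2). The diagonal slice
#' is the plane through the volume center obtained by pitching the axial
#' plane about the left-right axis, resampled bilinearly; its exact
#' geometry is a package convention (default pitch 45 degrees, running from
#' the frontal region down toward the posterior fossa).
#'
#' @param vol 3D numeric array (a trailing singleton 4th dimension is
#'   dropped).
#' @param plane `"axial"`, `"coronal"` or `"diagonal"`.
#' @param index 0-based slice index (axial: dim 3; coronal: dim 2);
#'   ignored for the diagonal plane.
#' @param pitch diagonal pitch in degrees.
#' @return numeric matrix with left-right along the columns.
#' @export
extractSlice <- function(vol, plane = c("axial", "coronal", "diagonal"),
                         index = 0L, pitch = 45) {
  vol <- .checkVolume(vol)
  plane <- match.arg(plane)
  d <- dim(vol)
  if (plane == "axial") {
    if (index < 0L || index >= d[3L])
      stop("axial index ", index, " out of range [0, ", d[3L] - 1L, "]",
           call. = FALSE)
    return(t(vol[, , index + 1L]))            # rows = AP, cols = LR
  }
  if (plane == "coronal") {
    if (index < 0L || index >= d[2L])
      stop("coronal index ", index, " out of range [0, ", d[2L] - 1L, "]",
           call. = FALSE)
    return(t(vol[, index + 1L, ]))            # rows = SI, cols = LR
  }
  ## diagonal: sample p(u, x) = center + (u - u0) * (0, cos(pitch),
  ## sin(pitch)) over u = 1..d2, bilinear in (AP, SI), zero outside
  th <- pitch * pi / 180
  u0 <- (d[2L] + 1) / 2; cy <- (d[2L] + 1) / 2; cz <- (d[3L] + 1) / 2
  u <- seq_len(d[2L])
  y <- cy + (u - u0) * cos(th)
  z <- cz + (u - u0) * sin(th)
  out <- matrix(0, d[2L], d[1L])
  y0 <- floor(y); z0 <- floor(z)
  fy <- y - y0;   fz <- z - z0
  ok <- y0 >= 1 & y0 + 1 <= d[2L] & z0 >= 1 & z0 + 1 <= d[3L]
  for (i in which(ok)) {
    out[i, ] <- (1 - fy[i]) * ((1 - fz[i]) * vol[, y0[i], z0[i]] +
                                 fz[i] * vol[, y0[i], z0[i] + 1L]) +
      fy[i] * ((1 - fz[i]) * vol[, y0[i] + 1L, z0[i]] +
                 fz[i] * vol[, y0[i] + 1L, z0[i] + 1L])
  }
  out
}

#' Default slice set for the asymmetry profile
#'
#' One diagonal slice, five axial slices (68, 78, 88, 98, 108) and five
#' coronal slices (84, 94, 104, 114, 124), spaced 10 voxels apart through
#' the central portion of the volume where the symmetry axis is least
#' ambiguous.
#'
#' @return data.frame with columns `name`, `plane`, `index`.
#' @export
defaultSliceSet <- function() {
  data.frame(
    name = .INDICATORS,
    plane = c("diagonal", rep("axial", 5L), rep("coronal", 5L)),
    index = c(NA_integer_, 68L, 78L, 88L, 98L, 108L,
              84L, 94L, 104L, 114L, 124L),
    stringsAsFactors = FALSE)
}

#' Asymmetry profile of one subject
#'
#' Runs [findSymmetryAxis()] on each slice of the slice set and assembles
#' the named per-slice asymmetry indices. Deterministic: the same volume
#' and configuration always give bit-identical profiles.
#'
#' @param vol 3D numeric array.
#' @param config an [axisSearchConfig()].
#' @param slices slice set as from [defaultSliceSet()]; custom sets (e.g.
#'   for smaller test volumes) must keep the `name`, `plane`, `index`
#'   columns.
#' @param subjectID character label.
#' @param pitch diagonal pitch in degrees, see [extractSlice()].
#' @return an [AsymmetryProfile-class] (validity enforces 11 indices for
#'   the default slice set; custom sets return a plain named vector inside
#'   the object only when they carry the 11 canonical names, otherwise use
#'   the returned diagnostics).
#' @export
profileSubject <- function(vol, config = axisSearchConfig(),
                           slices = defaultSliceSet(),
                           subjectID = "subject", pitch = 45) {
  vol <- .checkVolume(vol)
  idx <- numeric(nrow(slices))
  diag <- data.frame(slice = slices$name, angle = NA_real_,
                     dx = NA_integer_, dy = NA_integer_,
                     nCandidates = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(slices))) {
    sl <- extractSlice(vol, slices$plane[i],
                       if (is.na(slices$index[i])) 0L else slices$index[i],
                       pitch = pitch)
    if (sum(sl) <= 0)
      stop("degenerate (all-zero) ", slices$plane[i], " slice ",
           slices$index[i], " for subject '", subjectID, "'",
           call. = FALSE)
    r <- findSymmetryAxis(sl, config)
    idx[i] <- asymmetryIndex(r)
    diag$angle[i] <- axisAngle(r)
    diag$dx[i] <- r@dx; diag$dy[i] <- r@dy
    diag$nCandidates[i] <- candidatesEvaluated(r)
  }
  names(idx) <- slices$name
  if (identical(slices$name, .INDICATORS))
    new("AsymmetryProfile", subjectID = subjectID, indices = idx,
        diagnostics = diag)
  else
    structure(list(subjectID = subjectID, indices = idx,
                   diagnostics = diag), class = "sliceProfile")
}

#' @describeIn profileSubject named vector of slice asymmetry indices.
#' @param x an `AsymmetryProfile`.
#' @export
profileIndices <- function(x) {
  if (is(x, "AsymmetryProfile")) x@indices else x$indices
}

#' @describeIn profileSubject subject identifier.
#' @export
subjectID <- function(x) {
  if (is(x, "AsymmetryProfile")) x@subjectID else x$subjectID
}

#' @describeIn profileSubject per-slice search diagnostics.
#' @export
profileDiagnostics <- function(x) {
  if (is(x, "AsymmetryProfile")) x@diagnostics else x$diagnostics
}

setMethod("show", "AsymmetryProfile", function(object) {
  cat("AsymmetryProfile for subject '", object@subjectID, "'\n", sep = "")
  print(round(object@indices, 5))
})

#' Profile a cohort of volumes and merge covariates
#'
#' Computes the 11-indicator asymmetry profile for every subject and merges
#' the covariate table (age in years; sex coded female = 0, male = 1;
#' Hollingshead SES score 1--5). Subjects with missing covariates, SES
#' outside 1--5, unreadable volumes or degenerate slices are dropped with a
#' logged reason.
#'
#' @param volumes named list of 3D arrays, or a named character vector of
#'   NIfTI/Analyze file paths; names are subject IDs.
#' @param covariates data.frame with columns `subject_id`, `age`, `sex`,
#'   `ses`.
#' @param config,slices,pitch passed to [profileSubject()].
#' @param quiet suppress per-subject log messages.
#' @return data.frame with columns `subject_id`, the 11 indicators, `age`,
#'   `sex`, `ses` (fixed order), one row per retained subject.
#' @export
profileCohort <- function(volumes, covariates, config = axisSearchConfig(),
                          slices = defaultSliceSet(), pitch = 45,
                          quiet = FALSE) {
  need <- c("subject_id", "age", "sex", "ses")
  if (!all(need %in% names(covariates)))
    stop("covariate table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (anyDuplicated(covariates$subject_id))
    stop("duplicate subject_id in covariate table", call. = FALSE)
  ids <- names(volumes)
  if (length(volumes) && (is.null(ids) || anyDuplicated(ids)))
    stop("'volumes' must be uniquely named by subject_id", call. = FALSE)
  say <- function(...) if (!quiet) message(...)
  rows <- list()
  for (id in ids) {
    cv <- covariates[covariates$subject_id == id, , drop = FALSE]
    if (nrow(cv) != 1L || anyNA(cv[, need]) ||
        !(cv$ses %in% 1:5)) {
      say("dropping '", id, "': missing or invalid covariates")
      next
    }
    vol <- tryCatch(
      if (is.character(volumes[[id]])) readVolume(volumes[[id]])
      else volumes[[id]],
      error = function(e) e)
    if (inherits(vol, "error")) {
      say("dropping '", id, "': unreadable volume (",
          conditionMessage(vol), ")")
      next
    }
    pr <- tryCatch(
      profileSubject(vol, config, slices, subjectID = id, pitch = pitch),
      error = function(e) e)
    if (inherits(pr, "error")) {
      say("dropping '", id, "': ", conditionMessage(pr))
      next
    }
    rows[[id]] <- data.frame(subject_id = id,
                             as.list(profileIndices(pr)),
                             age = cv$age, sex = cv$sex, ses = cv$ses,
                             stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    warning("empty cohort after filtering", call. = FALSE)
    cols <- c("subject_id", slices$name, "age", "sex", "ses")
    out <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)),
                                  cols))
    out$subject_id <- character(0)
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize the composition of a covariate table
#'
#' Percentages of women and men and of each SES level, as customarily
#' reported for a study sample.
#'
#' @param covariates data.frame with `sex` (female = 0, male = 1) and
#'   `ses` columns.
#' @return list with `n`, `pctWomen`, `pctMen`, and `pctSES` (named vector
#'   over the observed SES levels, percentages to one decimal).
#' @export
cohortComposition <- function(covariates) {
  n <- nrow(covariates)
  ses <- table(factor(covariates$ses, levels = sort(unique(covariates$ses))))
  list(n = n,
       pctWomen = round(100 * sum(covariates$sex == 0) / n),
       pctMen = round(100 * sum(covariates$sex == 1) / n),
       pctSES = round(100 * as.vector(ses) / n, 1) |>
         setNames(names(ses)))
}
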
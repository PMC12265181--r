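## File input/output: 2D grayscale PNG/TIFF slices, NIfTI-1 / Analyze 7.5
## volumes, indicator CSV tables. Intensities are used as stored (the GMSD
## stability constant adapts to the dynamic range); no normalization.

#' Read a 2D grayscale image
#'
#' PNG via the png package, TIFF via the tiff package (if installed).
#' Multi-channel images are collapsed to grayscale by the channel mean; an
#' alpha channel is dropped. Intensities are returned as stored (0--1 for
#' PNG).
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return numeric matrix (rows = image rows).
#' @export
readGrayImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("package 'tiff' is required for TIFF input", call. = FALSE)
      tiff::readTIFF(path)
    },
    stop("unsupported image format '.", ext, "'", call. = FALSE))
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3L]
    if (nc == 2L || nc == 4L) nc <- nc - 1L   # drop alpha
    arr <- apply(arr[, , seq_len(nc), drop = FALSE], c(1L, 2L), mean)
  }
  arr
}

#' Write a 2D grayscale image as PNG
#'
#' Intensities are scaled by the image maximum into 0--1 (16-bit samples),
#' so the round trip reproduces intensities up to quantization.
#'
#' @param img numeric matrix.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeGrayImage <- function(img, path) {
  m <- max(img)
  png::writePNG(if (m > 0) img / m else img, path, dpi = NULL)
  invisible(path)
}

#' Read a 3D brain volume
#'
#' NIfTI-1 (`.nii`, `.nii.gz`) via RNifti; Analyze 7.5 (`.hdr`/`.img`) via
#' oro.nifti when installed. A trailing singleton channel dimension is
#' dropped; dimensions other than 176 x 208 x 176 produce a warning, not an
#' error.
#'
#' @param path volume file path.
#' @return 3D numeric array.
#' @export
readVolume <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  vol <- if (ext %in% c("hdr", "img")) {
    if (!requireNamespace("oro.nifti", quietly = TRUE))
      stop("package 'oro.nifti' is required for Analyze 7.5 input",
           call. = FALSE)
    as.array(oro.nifti::readANALYZE(sub("\\.(hdr|img)(\\.gz)?$", "", path)))
  } else as.array(RNifti::readNifti(path))
  .checkVolume(vol)
}

#' Write an indicator + covariate table as CSV
#'
#' Fixed column order (`subject_id`, the slice indicators, `age`, `sex`,
#' `ses`), no row names.
#'
#' @param table data.frame from [profileCohort()] or [simulateCohort()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeIndicatorTable <- function(table, path) {
  lead <- intersect(c("subject_id", .INDICATORS, "age", "sex", "ses"),
                    names(table))
  table <- table[, c(lead, setdiff(names(table), lead)), drop = FALSE]
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
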
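## End-to-end pipeline: volumes -> per-slice asymmetry profiles ->
## indicator table -> two-step MIMIC fit -> artifacts (CSV, JSON report,
## text summary). Deterministic given inputs and configuration; every
## artifact embeds the package version and a hash of the effective
## configuration.

.configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

#' Run the full asymmetry pipeline
#'
#' Profiles every subject ([profileCohort()]), writes the indicator table,
#' fits the two-step MIMIC model ([twoStepFit()]) and writes a JSON fit
#' report plus a plain-text summary laid out like the customary loadings /
#' coefficients / fit-index tables.
#'
#' @param volumes named list of 3D arrays or named vector of volume paths.
#' @param covariates covariate data.frame (`subject_id`, `age`, `sex`,
#'   `ses`) or a CSV path.
#' @param outDir output directory (created if needed).
#' @param config an [axisSearchConfig()].
#' @param spec a [MimicSpec-class]; indicator names must match the slice
#'   set.
#' @param slices slice set, see [profileSubject()].
#' @param pitch diagonal pitch in degrees.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with `table`, `fit` (the `twoStepFit`) and
#'   the artifact paths.
#' @export
runPipeline <- function(volumes, covariates, outDir,
                        config = axisSearchConfig(), spec = mimicSpec(),
                        slices = defaultSliceSet(), pitch = 45,
                        quiet = FALSE) {
  if (is.character(covariates) && length(covariates) == 1L)
    covariates <- utils::read.csv(covariates, stringsAsFactors = FALSE)
  if (!all(slices$name %in% spec@indicators) ||
      !all(spec@indicators %in% slices$name))
    stop("slice set and model indicators disagree", call. = FALSE)
  bad <- slices$index[!is.na(slices$index)]
  if (any(bad < 0L))
    stop("negative slice index in slice set", call. = FALSE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  eff <- list(package = "hemisym",
              version = as.character(utils::packageVersion("hemisym")),
              axis = unclass(config), pitch = pitch,
              slices = slices,
              indicators = spec@indicators, predictors = spec@predictors,
              residualCov = apply(spec@residualCov, 1L, paste,
                                  collapse = "~~"),
              identification = spec@identification)
  eff$configHash <- .configHash(eff)

  table <- profileCohort(volumes, covariates, config, slices, pitch,
                         quiet = quiet)
  if (!nrow(table))
    stop("no subjects survived profiling; nothing to fit", call. = FALSE)
  csv <- file.path(outDir, "indicators.csv")
  writeIndicatorTable(table, csv)

  fit <- twoStepFit(spec, data = table)
  std <- standardizedSolution(fit$structural$fit)
  report <- list(
    provenance = eff,
    n = fit$structural$fit@moments$n,
    cfa = list(indices = unclass(fit$cfa$indices),
               thresholds = fit$cfa$report),
    structural = list(
      indices = unclass(fit$structural$indices),
      thresholds = fit$structural$report,
      estimates = data.frame(param = names(coef(fit$structural$fit)),
                             est = unname(coef(fit$structural$fit)),
                             se = unname(semSE(fit$structural$fit))),
      standardized = std),
    modificationIndices = tryCatch(
      utils::head(modificationIndices(fit$structural$fit), 10L),
      error = function(e) conditionMessage(e)))
  jsonPath <- file.path(outDir, "fit_report.json")
  jsonlite::write_json(report, jsonPath, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE, pretty = TRUE)

  txt <- file.path(outDir, "summary.txt")
  lines <- c(
    sprintf("hemisym %s  (config %s)", eff$version, eff$configHash),
    sprintf("Subjects analyzed: %d", nrow(table)), "",
    "Standardized factor loadings",
    sprintf("  %-6s %6.2f", sub(".*=~", "", std$param[std$type == "loading"]),
            std$std[std$type == "loading"]), "",
    "Standardized regression coefficients",
    sprintf("  %-6s %6.2f", sub(".*~", "", std$param[std$type == "path"]),
            std$std[std$type == "path"]), "",
    "Model fit indices (structural model)",
    utils::capture.output(print(fit$structural$indices)))
  writeLines(lines, txt)
  invisible(list(table = table, fit = fit,
                 paths = c(indicators = csv, report = jsonPath,
                           summary = txt)))
}
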
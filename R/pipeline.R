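# End-to-end pipeline: read -> ladder -> calibrate -> annotate -> quantify,
# with TSV reports per stage and a machine-readable JSON summary.

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full GUI annotation/quantification pipeline
#'
#' Reads an mzML run (or accepts an \linkS4class{MSRun} directly), centroids
#' profile spectra, detects and assigns the dextrin ladder, fits the
#' calibration curve, annotates glycan compositions and quantifies isomer
#' peaks, writing one TSV per stage plus a JSON run summary to the output
#' directory. Re-running with identical input and configuration reproduces
#' the outputs byte for byte.
#'
#' @param input path to an mzML file, or an \linkS4class{MSRun}
#' @param config a \code{\link{guConfig}}
#' @param outDir output directory (created if absent); NULL to skip writing
#' @param compositions optional pre-enumerated composition list passed to
#'   \code{\link{annotateRun}}
#' @return invisibly, a list with elements run, index, ladder, model,
#'   annotations, quantification, summary
#' @export
runPipeline <- function(input, config = guConfig(), outDir = NULL,
                        compositions = NULL) {
  t0 <- proc.time()[["elapsed"]]
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline failed at the ", what, " stage: ", conditionMessage(e),
           call. = FALSE))
  }
  run <- if (is(input, "MSRun")) input else stage("input", readMzML(input))
  run@spectra <- lapply(run@spectra, centroidSpectrum)
  index <- stage("indexing", buildPeakIndex(run))
  tRead <- proc.time()[["elapsed"]]

  obs <- stage("ladder", extractLadderCandidates(run, index, config))
  tLadder <- proc.time()[["elapsed"]]

  calStage <- stage("calibration", {
    if (nrow(obs) == 0L)
      stop("no dextrin-ladder ions found in the run (GU ",
           min(config$guRange), "-", max(config$guRange),
           "); cannot calibrate")
    ladder <- assignLadder(obs, config$guRange)
    pts <- ladderAssignment(ladder)[, c("rt", "gu")]
    if (nrow(pts) < config$fitOrder + 1L)
      stop("only ", nrow(pts), " ladder rungs assigned; need at least ",
           config$fitOrder + 1L, " for a fit of order ", config$fitOrder)
    list(ladder = ladder, model = fitCalibration(pts, config$fitKind,
                                                 config$fitOrder))
  })
  ladder <- calStage$ladder
  model <- calStage$model
  tCal <- proc.time()[["elapsed"]]

  annotations <- stage("annotation",
                       annotateRun(run, index, model, config, compositions))
  tAnn <- proc.time()[["elapsed"]]
  quant <- stage("quantification",
                 quantifyRun(annotations, run, index, model, config))
  tQuant <- proc.time()[["elapsed"]]

  summary <- list(
    nSpectra = length(run@spectra), nMs1 = length(ms1Indices(run)),
    nLadderObservations = nrow(obs),
    nLadderRungs = nrow(ladderAssignment(ladder)),
    calibration = list(kind = model@kind, order = model@order,
                       rSquared = model@rSquared,
                       coefficients = model@coefficients),
    nAnnotations = nrow(annotations),
    nCompositions = length(unique(annotations$composition)),
    nIsomerPeaks = nrow(quant),
    stageSeconds = list(read = tRead - t0, ladder = tLadder - tRead,
                        calibrate = tCal - tLadder,
                        annotate = tAnn - tCal, quantify = tQuant - tAnn))

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    .writeTsv(ladder@observations, file.path(outDir, "ladder_observations.tsv"))
    .writeTsv(ladderAssignment(ladder), file.path(outDir, "ladder_assignment.tsv"))
    cal <- data.frame(term = paste0("beta", seq_along(model@coefficients) - 1L),
                      coefficient = model@coefficients)
    calPts <- model@fitPoints
    calPts$fittedGui <- as.numeric(rtToGUI(model, calPts$rt))
    .writeTsv(cal, file.path(outDir, "calibration_coefficients.tsv"))
    .writeTsv(calPts, file.path(outDir, "calibration_points.tsv"))
    .writeTsv(annotations, file.path(outDir, "annotations.tsv"))
    .writeTsv(quant, file.path(outDir, "quantification.tsv"))
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(run = run, index = index, ladder = ladder, model = model,
                 annotations = annotations, quantification = quant,
                 summary = summary))
}
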
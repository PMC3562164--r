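#' Pipeline configuration
#'
#' Bundles the file paths and stage settings of a full run. Round-trips
#' losslessly through JSON (\code{jsonlite}) apart from the class
#' attributes, which \code{\link{pipelineConfig}} restores.
#'
#' @param platePath path to the plate CSV (see \code{\link{readPlate}}).
#' @param panelPath path to the panel TSV; NULL uses the default panel.
#' @param outcomePath optional outcome records CSV
#'   (\code{specimen_id,endpoint,category}).
#' @param recordsPath optional specimen records CSV; when absent, every
#'   specimen present on the plate is treated as analyzed.
#' @param outDir output directory for the stage reports.
#' @param fit a \code{\link{fitConfig}}.
#' @param classify a \code{\link{classifyConfig}}.
#' @param seed seed recorded in the run log (the analysis itself is
#'   deterministic).
#' @return list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(platePath, panelPath = NULL, outcomePath = NULL,
                           recordsPath = NULL, outDir = ".",
                           fit = fitConfig(), classify = classifyConfig(),
                           seed = 1L) {
  structure(list(platePath = platePath, panelPath = panelPath,
                 outcomePath = outcomePath, recordsPath = recordsPath,
                 outDir = outDir, fit = fit, classify = classify,
                 seed = seed),
            class = "pipelineConfig")
}

#' Run the full chemosensitivity pipeline
#'
#' Executes normalize -> fit -> classify -> rank -> summarize on a plate
#' file, writing the classification report, the ranking report and a JSON
#' summary (all rates at full precision plus the reporting-rounded
#' values) into \code{outDir}. Deterministic given identical inputs and
#' configuration: reruns produce byte-identical reports.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return invisibly, a list with \code{classifications}, \code{rankings},
#'   \code{summary} and the report paths.
#' @export
runPipeline <- function(config) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  wells <- readPlate(config$platePath)
  if (nrow(wells) == 0) stop("pipeline error [read]: empty plate file",
                             call. = FALSE)
  panel <- if (is.null(config$panelPath)) {
    defaultPanel()
  } else {
    readPanel(config$panelPath)
  }

  sids <- unique(wells$specimen_id)
  classifications <- list()
  rankings <- list()
  for (sid in sids) {
    w <- wells[wells$specimen_id == sid, , drop = FALSE]
    ctrl <- w[w$drug == CONTROL_CODE, , drop = FALSE]
    drugs <- setdiff(unique(w$drug), CONTROL_CODE)
    cls <- list()
    for (d in drugs) {
      series <- tryCatch(
        normalizeViability(rbind(w[w$drug == d, , drop = FALSE], ctrl)),
        error = function(e) {
          stop(sprintf("pipeline error [normalize] %s/%s: %s",
                       sid, d, conditionMessage(e)), call. = FALSE)
        })
      cls[[d]] <- classifySeries(series, config = config$classify,
                                 fitCfg = config$fit)
    }
    classifications <- c(classifications, cls)
    rankings[[sid]] <- rankSpecimen(cls, panel)
  }

  records <- if (!is.null(config$recordsPath)) {
    read.csv(config$recordsPath, stringsAsFactors = FALSE)
  } else {
    data.frame(specimen_id = sids, source = "unknown",
               cells_sufficient = TRUE, exclusion_reason = "none",
               analyzed = TRUE, stringsAsFactors = FALSE)
  }
  outcomes <- if (!is.null(config$outcomePath)) {
    read.csv(config$outcomePath, stringsAsFactors = FALSE)
  } else {
    NULL
  }

  curves <- classificationTable(classifications, panel)
  summary <- cohortSummary(records, curves, outcomes)

  classPath <- file.path(config$outDir, "classification_report.csv")
  rankPath <- file.path(config$outDir, "ranking_report.csv")
  summaryPath <- file.path(config$outDir, "cohort_summary.json")
  writeClassificationReport(classifications, classPath)
  writeRankingReport(rankings, rankPath)
  jsonlite::write_json(
    list(seed = config$seed,
         nSpecimens = length(sids),
         nCurves = nrow(curves),
         informativeRate = summary$informativeRate,
         patternTotals = as.list(summary$patternFrequency$totals),
         patternFractions = as.list(summary$patternFrequency$fractions),
         informativeCurveFraction = summary$patternFrequency$informativeFraction,
         ppcExceedance = summary$ppcExceedance,
         respondedFraction = as.list(summary$respondedFraction)),
    summaryPath, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")

  invisible(list(classifications = classifications, rankings = rankings,
                 summary = summary,
                 paths = c(classification = classPath, ranking = rankPath,
                           summary = summaryPath)))
}
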
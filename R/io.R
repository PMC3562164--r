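#' Read a plate CSV of well measurements
#'
#' Dialect: comma-separated, UTF-8, "." decimal separator, header
#' \code{specimen_id,drug,concentration_uM,replicate,absorbance}. Control
#' wells carry drug code \code{CONTROL} and an empty concentration field.
#' Malformed rows are reported with their line numbers.
#'
#' @param path path to the plate CSV.
#' @return validated well-measurement data.frame.
#' @export
readPlate <- function(path) {
  stopIfNot(file.exists(path), sprintf("plate file not found: %s", path))
  required <- c("specimen_id", "drug", "concentration_uM", "replicate",
                "absorbance")
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (!all(required %in% header)) {
    stop(sprintf("plate format error: expected header %s",
                 paste(required, collapse = ",")), call. = FALSE)
  }
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(specimen_id = "character",
                                drug = "character",
                                concentration_uM = "numeric",
                                replicate = "integer",
                                absorbance = "numeric"))
  if (nrow(df) == 0) {
    warning("plate file contains a header but no data rows")
    return(df)
  }
  # line numbers are 1-based including the header line
  line <- seq_len(nrow(df)) + 1L
  bad <- !is.na(df$absorbance) & df$absorbance < 0
  if (any(bad)) {
    stop(sprintf("validation error: negative absorbance at line(s) %s",
                 paste(line[bad], collapse = ", ")), call. = FALSE)
  }
  treated <- df$drug != CONTROL_CODE
  bad <- treated & (is.na(df$concentration_uM) | df$concentration_uM <= 0)
  if (any(bad)) {
    stop(sprintf(
      "validation error: treated wells need a positive concentration at line(s) %s",
      paste(line[bad], collapse = ", ")), call. = FALSE)
  }
  bad <- is.na(df$absorbance)
  if (any(bad)) {
    stop(sprintf("validation error: missing absorbance at line(s) %s",
                 paste(line[bad], collapse = ", ")), call. = FALSE)
  }
  df
}

#' Write a plate CSV
#' @param wells well-measurement data.frame.
#' @param path output path.
#' @export
writePlate <- function(wells, path) {
  write.csv(wells, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write the classification report CSV
#'
#' Columns: \code{specimen_id,drug,pattern,informative,gi50_uM,
#' gi50_in_range,r2_adj,aicc}.
#'
#' @param classifications list of \linkS4class{CurveClassification}.
#' @param path output path.
#' @export
writeClassificationReport <- function(classifications, path) {
  df <- classificationTable(classifications)
  names(df)[names(df) == "gi50"] <- "gi50_uM"
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write the ranking report CSV
#'
#' Columns: \code{specimen_id,drug,status,rank,gi50_uM,ppc_uM,score,
#' low_confidence}, where status is ranked, resistant or unevaluable.
#'
#' @param rankings list of \linkS4class{SensitivityRanking}.
#' @param path output path.
#' @export
writeRankingReport <- function(rankings, path) {
  rows <- do.call(rbind, lapply(rankings, function(r) {
    out <- list()
    if (nrow(r@ranked)) {
      out[[1]] <- data.frame(specimen_id = r@specimenId,
                             drug = r@ranked$drug, status = "ranked",
                             rank = r@ranked$rank,
                             gi50_uM = r@ranked$gi50, ppc_uM = r@ranked$ppc,
                             score = r@ranked$score,
                             low_confidence = r@ranked$lowConfidence)
    }
    if (length(r@resistant)) {
      out[[length(out) + 1]] <- data.frame(
        specimen_id = r@specimenId, drug = r@resistant,
        status = "resistant", rank = NA_integer_, gi50_uM = NA_real_,
        ppc_uM = NA_real_, score = NA_real_, low_confidence = NA)
    }
    if (nrow(r@unevaluable)) {
      out[[length(out) + 1]] <- data.frame(
        specimen_id = r@specimenId, drug = r@unevaluable$drug,
        status = "unevaluable", rank = NA_integer_,
        gi50_uM = r@unevaluable$gi50, ppc_uM = NA_real_,
        score = NA_real_, low_confidence = NA)
    }
    do.call(rbind, out)
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
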
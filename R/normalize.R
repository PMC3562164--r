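#' Normalize raw well absorbances to a dose-response series
#'
#' Converts the WST absorbances of one specimen-drug pair into
#' control-normalized viabilities: the viability at each concentration is
#' the mean replicate absorbance divided by the mean absorbance of the
#' specimen's untreated control wells. Wells whose individual viability
#' exceeds \code{outlierViability} are flagged as outliers and dropped
#' (growth stimulation slightly above control is common in primary culture
#' and retained; gross excursions are treated as technical failures).
#'
#' @param wells data.frame of well measurements with columns
#'   \code{specimen_id}, \code{drug}, \code{concentration_uM},
#'   \code{replicate}, \code{absorbance}; control wells carry drug code
#'   \code{"CONTROL"} and NA concentration. Must contain exactly one
#'   treated drug plus that specimen's control wells.
#' @param outlierViability wells above this viability are dropped
#'   (default 1.5).
#' @return a \linkS4class{DoseResponseSeries}.
#' @examples
#' wells <- data.frame(
#'   specimen_id = "GC-001",
#'   drug = c(rep("CIS", 9), rep("CONTROL", 3)),
#'   concentration_uM = c(rep(c(16.7, 1.67, 0.167), each = 3), rep(NA, 3)),
#'   replicate = rep(1:3, 4),
#'   absorbance = c(0.30, 0.32, 0.28, 0.60, 0.62, 0.58,
#'                  0.75, 0.80, 0.85, 0.78, 0.80, 0.82)
#' )
#' s <- normalizeViability(wells)
#' viability(s)
#' @export
normalizeViability <- function(wells, outlierViability = 1.5) {
  required <- c("specimen_id", "drug", "concentration_uM", "replicate",
                "absorbance")
  stopIfNot(all(required %in% names(wells)),
            "well table must have columns specimen_id, drug, concentration_uM, replicate, absorbance")
  stopIfNot(all(wells$absorbance >= 0, na.rm = TRUE),
            "validation error: negative absorbance")
  ctrl <- wells[wells$drug == CONTROL_CODE, , drop = FALSE]
  trt <- wells[wells$drug != CONTROL_CODE, , drop = FALSE]
  if (nrow(ctrl) == 0) stop("missing-control error: no control wells", call. = FALSE)
  drug <- unique(trt$drug)
  stopIfNot(length(drug) == 1,
            "well table must contain exactly one treated drug")
  sid <- unique(wells$specimen_id)
  stopIfNot(length(sid) == 1, "well table must contain a single specimen")
  stopIfNot(all(trt$concentration_uM > 0),
            "validation error: treated wells need positive concentrations")

  cm <- mean(ctrl$absorbance)
  if (!is.finite(cm) || cm <= 0) {
    stop("degenerate-control error: control mean must be positive",
         call. = FALSE)
  }

  conc <- sort(unique(trt$concentration_uM))
  rep_v <- lapply(conc, function(cc) {
    v <- trt$absorbance[trt$concentration_uM == cc] / cm
    v[v <= outlierViability]  # drop outlier wells
  })
  keep <- lengths(rep_v) > 0
  conc <- conc[keep]
  rep_v <- rep_v[keep]
  if (length(conc) < 3) {
    stop("insufficient-series error: fewer than 3 usable concentrations",
         call. = FALSE)
  }
  new("DoseResponseSeries",
      specimenId = sid, drug = drug,
      concentrations = conc,
      viability = vapply(rep_v, mean, numeric(1)),
      replicateViability = rep_v,
      controlMean = cm)
}

#' Construct a DoseResponseSeries directly from viabilities
#'
#' Convenience constructor used by simulations and tests when well-level
#' absorbances are not needed.
#'
#' @param specimenId,drug identifiers.
#' @param concentrations ascending positive concentrations (uM).
#' @param viability per-concentration mean viabilities.
#' @param replicateViability optional list of replicate viabilities.
#' @param controlMean control absorbance (informational; default 1).
#' @return a \linkS4class{DoseResponseSeries}.
#' @export
doseResponseSeries <- function(specimenId, drug, concentrations, viability,
                               replicateViability = list(),
                               controlMean = 1) {
  o <- order(concentrations)
  new("DoseResponseSeries",
      specimenId = specimenId, drug = drug,
      concentrations = concentrations[o],
      viability = viability[o],
      replicateViability = if (length(replicateViability)) {
        replicateViability[o]
      } else list(),
      controlMean = controlMean)
}
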
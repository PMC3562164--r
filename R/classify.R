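#' Classification thresholds
#'
#' @param r2AdjGate minimum adjusted R-squared of the winning fit for a
#'   non-constant family; below it the series is noise-dominant. (The gate
#'   is not applied to the straight family, whose adjusted R-squared
#'   against near-constant data is ~0 by construction; flat series are
#'   gated on residual scatter alone.)
#' @param residSdGate maximum residual standard deviation of the winning
#'   fit; above it the series is noise-dominant.
#' @param logisticMinRange minimum fitted dynamic range (top - bottom) for
#'   a logistic classification.
#' @param hyperbolicFlatMean minimum mean viability over all-but-top doses
#'   for a hyperbolic classification.
#' @param hyperbolicFlatSpread maximum viability spread (max - min) over
#'   all-but-top doses for a hyperbolic classification.
#' @param hyperbolicTopDrop minimum drop of the top-dose viability below
#'   the all-but-top mean for a hyperbolic classification (the "steep drop
#'   at the highest dose" that defines the pattern).
#' @param minDecline minimum fitted decline across the tested range for
#'   exponential/linear classifications.
#' @param aicTieTolerance fits whose AIC lies within this margin of the
#'   minimum are treated as statistically indistinguishable ("equivalent
#'   support"); among them the family with fewer parameters wins, then the
#'   fixed family order. 0 reduces to exact-tie breaking only.
#' @return list of class \code{classifyConfig}.
#' @export
classifyConfig <- function(r2AdjGate = 0.5, residSdGate = 0.25,
                           logisticMinRange = 0.2,
                           hyperbolicFlatMean = 0.7,
                           hyperbolicFlatSpread = 0.15,
                           hyperbolicTopDrop = 0.2,
                           minDecline = 0.2,
                           aicTieTolerance = 2) {
  structure(list(r2AdjGate = r2AdjGate, residSdGate = residSdGate,
                 logisticMinRange = logisticMinRange,
                 hyperbolicFlatMean = hyperbolicFlatMean,
                 hyperbolicFlatSpread = hyperbolicFlatSpread,
                 hyperbolicTopDrop = hyperbolicTopDrop,
                 minDecline = minDecline,
                 aicTieTolerance = aicTieTolerance),
            class = "classifyConfig")
}

#' Classify a dose-response series into a shape pattern
#'
#' Among the valid (converged) fits, the minimum-AIC fit is located; fits
#' whose AIC lies within \code{aicTieTolerance} of it have equivalent
#' statistical support, and the simplest of those (fewest parameters, then
#' a fixed family order) becomes the candidate. A candidate failing its
#' data-level shape-validity check is removed and selection repeats on the
#' remaining fits. The surviving candidate must pass the noise gate
#' (adjusted R-squared and residual SD thresholds) for its family to
#' become the pattern; otherwise the series is noise-dominant. Logistic
#' classifications carry the absolute GI50 when the fitted curve crosses
#' viability 0.5.
#'
#' @param series a \linkS4class{DoseResponseSeries}.
#' @param fits named list of \linkS4class{CurveFit} (default: fit all
#'   families).
#' @param config a \code{\link{classifyConfig}}.
#' @param fitCfg a \code{\link{fitConfig}} used when \code{fits} is NULL.
#' @return a \linkS4class{CurveClassification}.
#' @export
classifySeries <- function(series, fits = NULL, config = classifyConfig(),
                           fitCfg = fitConfig()) {
  if (is.null(fits)) fits <- fitAllFamilies(series, fitCfg)
  stopIfNot(length(fits) > 0, "classification error: empty fit set")

  valid <- Filter(function(f) isTRUE(f@converged) && is.finite(f@aic), fits)
  candidate <- NULL
  while (length(valid)) {
    aics <- vapply(valid, function(f) f@aic, numeric(1))
    near <- which(aics <= min(aics) + config$aicTieTolerance)
    fams <- vapply(valid[near], function(f) f@family, character(1))
    pick <- near[order(familyNPar[fams], familyOrder[fams], aics[near])[1]]
    if (familyValidity(valid[[pick]]@family, valid[[pick]], series, config)) {
      candidate <- valid[[pick]]
      break
    }
    valid <- valid[-pick]
  }

  pattern <- "noise_dominant"
  if (!is.null(candidate)) {
    gate_r2 <- candidate@family == "straight" ||
      candidate@r2Adj >= config$r2AdjGate
    if (gate_r2 && candidate@residSd <= config$residSdGate) {
      pattern <- candidate@family
    }
  }

  g <- NA_real_
  g_in <- NA
  if (pattern == "logistic") {
    gg <- gi50FromLogistic(candidate, range(series@concentrations))
    g <- gg$gi50
    g_in <- gg$inRange
  }
  new("CurveClassification",
      specimenId = series@specimenId, drug = series@drug,
      pattern = pattern,
      informative = pattern %in% INFORMATIVE_PATTERNS,
      resistant = pattern == "hyperbolic",
      gi50 = g, gi50InRange = g_in,
      bestFit = if (pattern == "noise_dominant") NULL else candidate)
}

#' Is a classified curve informative?
#'
#' Only logistic (drug-dependent viability) and hyperbolic (drug
#' resistance) patterns enter the chemosensitivity evaluation; all other
#' patterns are eliminated from it.
#'
#' @param classification a \linkS4class{CurveClassification}.
#' @return logical(1).
#' @export
isInformative <- function(classification) {
  stopIfNot(methods::is(classification, "CurveClassification"),
            "expected a CurveClassification")
  classification@pattern %in% INFORMATIVE_PATTERNS
}
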
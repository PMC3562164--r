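#' DoseResponseSeries: one specimen-drug dilution series
#'
#' Control-normalized viabilities for one drug assayed on one specimen.
#' Viability is the mean replicate absorbance at a concentration divided by
#' the mean absorbance of that specimen's untreated control wells.
#'
#' @slot specimenId character(1) specimen identifier.
#' @slot drug character(1) drug code.
#' @slot concentrations numeric, strictly positive, strictly ascending (uM).
#' @slot viability numeric, per-concentration mean viability (fraction of
#'   control, >= 0).
#' @slot replicateViability list of numeric vectors, replicate-level
#'   viabilities per concentration (retained for QC and simulation only;
#'   fitting uses the means).
#' @slot controlMean numeric(1) mean control absorbance (> 0).
#' @exportClass DoseResponseSeries
setClass("DoseResponseSeries",
  representation(
    specimenId = "character",
    drug = "character",
    concentrations = "numeric",
    viability = "numeric",
    replicateViability = "list",
    controlMean = "numeric"
  )
)

setValidity("DoseResponseSeries", function(object) {
  msg <- character()
  n <- length(object@concentrations)
  if (n < 3) msg <- c(msg, "at least 3 distinct concentrations required")
  if (any(object@concentrations <= 0)) {
    msg <- c(msg, "concentrations must be strictly positive")
  }
  if (n > 1 && any(diff(object@concentrations) <= 0)) {
    msg <- c(msg, "concentrations must be strictly ascending")
  }
  if (length(object@viability) != n) {
    msg <- c(msg, "viability length must match concentrations")
  }
  if (any(object@viability < 0)) msg <- c(msg, "viability must be >= 0")
  if (length(object@controlMean) != 1 || object@controlMean <= 0) {
    msg <- c(msg, "controlMean must be a single positive value")
  }
  if (length(object@replicateViability) != 0 &&
      length(object@replicateViability) != n) {
    msg <- c(msg, "replicateViability must be empty or match concentrations")
  }
  if (length(msg)) msg else TRUE
})

#' CurveFit: a fitted candidate curve family
#'
#' Least-squares parameter estimates for one family on the per-concentration
#' mean viabilities of a series, with fit-quality metrics used for model
#' selection.
#'
#' @slot family character(1), one of logistic, hyperbolic, straight,
#'   exponential, linear.
#' @slot parameters named numeric vector on the natural scale
#'   (concentrations in uM).
#' @slot rss numeric(1) residual sum of squares (>= 0).
#' @slot r2Adj numeric(1) adjusted coefficient of determination.
#' @slot aic numeric(1) Akaike information criterion
#'   (n log(RSS/n) + 2p); the model-selection criterion.
#' @slot aicc numeric(1) small-sample corrected information criterion,
#'   reported alongside (Inf when the correction is undefined at this n).
#' @slot nPoints integer(1) number of concentration points fitted.
#' @slot residSd numeric(1) residual standard deviation,
#'   sqrt(rss / (n - p)).
#' @slot converged logical(1) whether the optimizer converged to a valid
#'   parameter vector; non-converged fits are excluded from selection.
#' @exportClass CurveFit
setClass("CurveFit",
  representation(
    family = "character",
    parameters = "numeric",
    rss = "numeric",
    r2Adj = "numeric",
    aic = "numeric",
    aicc = "numeric",
    nPoints = "integer",
    residSd = "numeric",
    converged = "logical"
  )
)

setValidity("CurveFit", function(object) {
  msg <- character()
  if (!object@family %in% CURVE_FAMILIES) {
    msg <- c(msg, sprintf("unknown family '%s'", object@family))
  }
  if (length(object@rss) != 1 || is.na(object@rss) || object@rss < -1e-12) {
    msg <- c(msg, "rss must be a single non-negative value")
  }
  if (length(msg)) msg else TRUE
})

#' CurveClassification: assigned pattern for one series
#'
#' @slot specimenId character(1).
#' @slot drug character(1).
#' @slot pattern character(1), one of the six patterns (five families plus
#'   noise_dominant).
#' @slot informative logical(1), TRUE iff pattern is logistic or hyperbolic.
#' @slot resistant logical(1), TRUE iff pattern is hyperbolic.
#' @slot gi50 numeric(1) in uM, NA unless pattern is logistic and the
#'   fitted curve crosses viability 0.5.
#' @slot gi50InRange logical(1), whether the GI50 lies within the tested
#'   concentration range (NA when gi50 is NA).
#' @slot bestFit the selected \linkS4class{CurveFit}, or NULL for
#'   noise-dominant series with no admissible fit.
#' @exportClass CurveClassification
setClass("CurveClassification",
  representation(
    specimenId = "character",
    drug = "character",
    pattern = "character",
    informative = "logical",
    resistant = "logical",
    gi50 = "numeric",
    gi50InRange = "logical",
    bestFit = "ANY"
  )
)

setValidity("CurveClassification", function(object) {
  msg <- character()
  if (!object@pattern %in% CURVE_PATTERNS) {
    msg <- c(msg, sprintf("unknown pattern '%s'", object@pattern))
  }
  if (!identical(object@informative,
                 object@pattern %in% INFORMATIVE_PATTERNS)) {
    msg <- c(msg, "informative must hold iff pattern is logistic/hyperbolic")
  }
  if (!identical(object@resistant, object@pattern == "hyperbolic")) {
    msg <- c(msg, "resistant must hold iff pattern is hyperbolic")
  }
  if (!is.na(object@gi50)) {
    if (object@pattern != "logistic") {
      msg <- c(msg, "gi50 may be present only for logistic pattern")
    }
    if (object@gi50 <= 0) msg <- c(msg, "gi50 must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' SensitivityRanking: within-specimen drug ordering by ppc/GI50 margin
#'
#' Every assayed drug lands in exactly one of three compartments: ranked
#' (logistic pattern with GI50 and a known ppc), resistant (hyperbolic
#' pattern), or unevaluable (anything else).
#'
#' @slot specimenId character(1).
#' @slot ranked data.frame with columns drug, gi50, ppc, score, rank,
#'   lowConfidence; rows ordered by rank.
#' @slot resistant character vector of drug codes with hyperbolic pattern.
#' @slot unevaluable data.frame with columns drug, reason, gi50.
#' @exportClass SensitivityRanking
setClass("SensitivityRanking",
  representation(
    specimenId = "character",
    ranked = "data.frame",
    resistant = "character",
    unevaluable = "data.frame"
  )
)

setValidity("SensitivityRanking", function(object) {
  msg <- character()
  rk <- object@ranked
  if (nrow(rk)) {
    if (!identical(rk$rank, seq_len(nrow(rk)))) {
      msg <- c(msg, "ranks must be contiguous 1..n in order")
    }
    if (any(diff(rk$score) > 1e-12)) {
      msg <- c(msg, "scores must be non-increasing with rank")
    }
  }
  all_drugs <- c(rk$drug, object@resistant, object@unevaluable$drug)
  if (anyDuplicated(all_drugs)) {
    msg <- c(msg, "each drug must appear in exactly one compartment")
  }
  if (length(msg)) msg else TRUE
})

#' @exportMethod show
setMethod("show", "DoseResponseSeries", function(object) {
  cat(sprintf(
    "DoseResponseSeries: specimen %s, drug %s\n  %d concentrations [%.4g .. %.4g uM], control mean %.3f\n  viability: %s\n",
    object@specimenId, object@drug, length(object@concentrations),
    min(object@concentrations), max(object@concentrations),
    object@controlMean,
    paste(sprintf("%.3f", object@viability), collapse = " ")
  ))
})

setMethod("show", "CurveFit", function(object) {
  cat(sprintf(
    "CurveFit [%s]%s: rss %.4g, adj-R2 %.3f, AIC %.4g (n = %d)\n  %s\n",
    object@family, if (object@converged) "" else " (non-convergent)",
    object@rss, object@r2Adj, object@aic, object@nPoints,
    paste(sprintf("%s = %.4g", names(object@parameters), object@parameters),
          collapse = ", ")
  ))
})

setMethod("show", "CurveClassification", function(object) {
  cat(sprintf(
    "CurveClassification: specimen %s, drug %s -> %s%s%s\n",
    object@specimenId, object@drug, object@pattern,
    if (object@informative) " [informative]" else "",
    if (!is.na(object@gi50)) {
      sprintf(", GI50 = %.4g uM%s", object@gi50,
              if (isTRUE(object@gi50InRange)) "" else " (out of tested range)")
    } else ""
  ))
})

setMethod("show", "SensitivityRanking", function(object) {
  cat(sprintf("SensitivityRanking: specimen %s\n", object@specimenId))
  if (nrow(object@ranked)) {
    for (i in seq_len(nrow(object@ranked))) {
      r <- object@ranked[i, ]
      cat(sprintf("  rank %d: %s (GI50 %.4g uM, ppc %.4g uM, score %+.3f)\n",
                  r$rank, r$drug, r$gi50, r$ppc, r$score))
    }
  } else {
    cat("  no ranked drugs\n")
  }
  if (length(object@resistant)) {
    cat("  resistant:", paste(object@resistant, collapse = ", "), "\n")
  }
  if (nrow(object@unevaluable)) {
    cat("  unevaluable:", paste(object@unevaluable$drug, collapse = ", "), "\n")
  }
})
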
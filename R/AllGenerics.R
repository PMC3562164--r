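#' @name accessors
#' @title Accessors for chemoRank S4 objects
#' @description Small accessor generics; user code should use these rather
#'   than reaching into slots.
#' @param object a chemoRank S4 object.
NULL

#' @rdname accessors
#' @export
setGeneric("specimenId", function(object) standardGeneric("specimenId"))
#' @rdname accessors
#' @export
setGeneric("drugCode", function(object) standardGeneric("drugCode"))
#' @rdname accessors
#' @export
setGeneric("concentrations", function(object) standardGeneric("concentrations"))
#' @rdname accessors
#' @export
setGeneric("viability", function(object) standardGeneric("viability"))
#' @rdname accessors
#' @export
setGeneric("controlMean", function(object) standardGeneric("controlMean"))
#' @rdname accessors
#' @export
setGeneric("curveFamily", function(object) standardGeneric("curveFamily"))
#' @rdname accessors
#' @export
setGeneric("fitParameters", function(object) standardGeneric("fitParameters"))
#' @rdname accessors
#' @export
setGeneric("fitRss", function(object) standardGeneric("fitRss"))
#' @rdname accessors
#' @export
setGeneric("fitAic", function(object) standardGeneric("fitAic"))
#' @rdname accessors
#' @export
setGeneric("fitAicc", function(object) standardGeneric("fitAicc"))
#' @rdname accessors
#' @export
setGeneric("curvePattern", function(object) standardGeneric("curvePattern"))
#' @rdname accessors
#' @export
setGeneric("gi50", function(object) standardGeneric("gi50"))
#' @rdname accessors
#' @export
setGeneric("bestFit", function(object) standardGeneric("bestFit"))
#' @rdname accessors
#' @export
setGeneric("rankedDrugs", function(object) standardGeneric("rankedDrugs"))
#' @rdname accessors
#' @export
setGeneric("resistantDrugs", function(object) standardGeneric("resistantDrugs"))
#' @rdname accessors
#' @export
setGeneric("unevaluableDrugs", function(object) standardGeneric("unevaluableDrugs"))

#' @rdname accessors
setMethod("specimenId", "DoseResponseSeries", function(object) object@specimenId)
#' @rdname accessors
setMethod("specimenId", "CurveClassification", function(object) object@specimenId)
#' @rdname accessors
setMethod("specimenId", "SensitivityRanking", function(object) object@specimenId)
#' @rdname accessors
setMethod("drugCode", "DoseResponseSeries", function(object) object@drug)
#' @rdname accessors
setMethod("drugCode", "CurveClassification", function(object) object@drug)
#' @rdname accessors
setMethod("concentrations", "DoseResponseSeries", function(object) object@concentrations)
#' @rdname accessors
setMethod("viability", "DoseResponseSeries", function(object) object@viability)
#' @rdname accessors
setMethod("controlMean", "DoseResponseSeries", function(object) object@controlMean)
#' @rdname accessors
setMethod("curveFamily", "CurveFit", function(object) object@family)
#' @rdname accessors
setMethod("fitParameters", "CurveFit", function(object) object@parameters)
#' @rdname accessors
setMethod("fitRss", "CurveFit", function(object) object@rss)
#' @rdname accessors
setMethod("fitAic", "CurveFit", function(object) object@aic)
#' @rdname accessors
setMethod("fitAicc", "CurveFit", function(object) object@aicc)
#' @rdname accessors
setMethod("curvePattern", "CurveClassification", function(object) object@pattern)
#' @rdname accessors
setMethod("gi50", "CurveClassification", function(object) object@gi50)
#' @rdname accessors
setMethod("bestFit", "CurveClassification", function(object) object@bestFit)
#' @rdname accessors
setMethod("rankedDrugs", "SensitivityRanking", function(object) object@ranked)
#' @rdname accessors
setMethod("resistantDrugs", "SensitivityRanking", function(object) object@resistant)
#' @rdname accessors
setMethod("unevaluableDrugs", "SensitivityRanking", function(object) object@unevaluable)
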
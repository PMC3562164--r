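#' Informative rate of a specimen cohort
#'
#' The informative rate is the fraction of specimens that produced usable
#' (analyzed) dose-response data: overall among all collected specimens,
#' and restricted to specimens that yielded a sufficient number of cells
#' for the viability assay.
#'
#' @param records data.frame of specimen records with columns
#'   \code{specimen_id}, \code{source} ("ascites"/"solid"),
#'   \code{cells_sufficient} (logical), \code{exclusion_reason}
#'   ("none", "low_viability", "fungal_contamination",
#'   "bacterial_contamination"), \code{analyzed} (logical).
#' @return list with \code{overall} and \code{sufficient}, percentages
#'   rounded to 1 decimal for reporting.
#' @examples
#' rec <- referenceCohort()
#' informativeRate(rec)  # overall 67.4, sufficient 85.3
#' @export
informativeRate <- function(records) {
  stopIfNot(nrow(records) >= 1, "at least one specimen record required")
  bad <- records$analyzed & (!records$cells_sufficient |
                               records$exclusion_reason != "none")
  stopIfNot(!any(bad),
            "invalid records: analyzed specimens must be cell-sufficient and unexcluded")
  n_suff <- sum(records$cells_sufficient)
  stopIfNot(n_suff > 0, "undefined rate: no cell-sufficient specimens")
  n_an <- sum(records$analyzed)
  list(overall = pct(n_an, nrow(records), 1),
       sufficient = pct(n_an, n_suff, 1))
}

#' Curve-type frequency table
#'
#' Per-drug counts of each pattern, with per-pattern column totals and the
#' column's fraction of all curves, plus the informative fraction
#' (logistic + hyperbolic over all curves).
#'
#' @param curves data.frame with one row per classified curve, columns
#'   \code{drug} and \code{pattern} (see \code{\link{classificationTable}}).
#' @return list with \code{counts} (drug x pattern matrix),
#'   \code{totals} (per-pattern counts), \code{fractions} (per-pattern \%
#'   of all curves, 1 decimal), \code{columnFractions} (within-pattern
#'   per-drug \%, 1 decimal), \code{informativeFraction} (\%, 1 decimal),
#'   \code{nCurves}.
#' @export
curveTypeFrequency <- function(curves) {
  stopIfNot(nrow(curves) >= 1, "at least one classification required")
  stopIfNot(all(curves$pattern %in% CURVE_PATTERNS),
            "unknown pattern in classification table")
  drugs <- unique(curves$drug)
  counts <- table(factor(curves$drug, levels = drugs),
                  factor(curves$pattern, levels = CURVE_PATTERNS))
  counts <- matrix(as.integer(counts), nrow = length(drugs),
                   dimnames = list(drugs, CURVE_PATTERNS))
  totals <- colSums(counts)
  n <- sum(totals)
  colfrac <- counts
  for (j in seq_along(CURVE_PATTERNS)) {
    colfrac[, j] <- if (totals[j] > 0) {
      roundHalfUp(100 * counts[, j] / totals[j], 1)
    } else {
      0
    }
  }
  list(counts = counts,
       totals = totals,
       fractions = roundHalfUp(100 * totals / n, 1),
       columnFractions = colfrac,
       informativeFraction = pct(sum(totals[INFORMATIVE_PATTERNS]), n, 1),
       nCurves = n)
}

#' Curves per analyzed specimen
#'
#' @param curves classification table (columns \code{specimen_id},
#'   \code{drug}, \code{pattern}).
#' @param records specimen records (see \code{\link{informativeRate}}).
#' @param source optional source filter ("ascites" or "solid").
#' @return curves per analyzed case, rounded to 1 decimal.
#' @export
drugsPerSpecimen <- function(curves, records, source = NULL) {
  if (!is.null(source)) records <- records[records$source == source, , drop = FALSE]
  ids <- records$specimen_id[records$analyzed]
  if (length(ids) == 0) {
    stop("undefined rate: no analyzed specimens in this source",
         call. = FALSE)
  }
  n_curves <- sum(curves$specimen_id %in% ids)
  roundHalfUp(n_curves / length(ids), 1)
}

#' Categorize a pre/post tumor-marker transition
#'
#' Up: the marker rises beyond the upper limit of normal (ULN) from within
#' or below it. Down: it falls to or below the ULN from above. Stable: it
#' stays at or below the ULN. The remaining case (above the ULN both
#' before and after) is mapped to Stable with an above-range flag, so that
#' every case receives a category.
#'
#' @param pre,post marker values (>= 0).
#' @param uln upper limit of the normal range (> 0).
#' @return list with \code{category} ("Up", "Stable", "Down") and
#'   \code{aboveRange} (logical flag for the both-above case).
#' @export
categorizeMarker <- function(pre, post, uln) {
  if (missing(uln) || is.na(uln) || length(uln) != 1 || uln <= 0) {
    stop("configuration error: a positive upper limit of normal is required",
         call. = FALSE)
  }
  stopIfNot(pre >= 0 && post >= 0, "marker values must be non-negative")
  if (pre <= uln && post > uln) {
    list(category = "Up", aboveRange = FALSE)
  } else if (pre > uln && post <= uln) {
    list(category = "Down", aboveRange = FALSE)
  } else if (pre <= uln && post <= uln) {
    list(category = "Stable", aboveRange = FALSE)
  } else {
    list(category = "Stable", aboveRange = TRUE)
  }
}

#' Responded fraction for one outcome endpoint
#'
#' Tumor markers and ascites volume count Stable + Down as a response
#' (the burden did not progress); dietary intake counts Up (improved
#' intake). Reported as a percentage rounded to the nearest integer.
#'
#' @param outcomes data.frame with columns \code{specimen_id},
#'   \code{endpoint}, \code{category} ("Up"/"Stable"/"Down").
#' @param endpoint one of "CEA", "CA19-9", "ascites_volume", "diet".
#' @return percentage (integer-rounded).
#' @export
respondedFraction <- function(outcomes, endpoint) {
  ok_ep <- c("CEA", "CA19-9", "ascites_volume", "diet")
  if (!endpoint %in% ok_ep) {
    stop(sprintf("configuration error: unknown endpoint '%s'", endpoint),
         call. = FALSE)
  }
  x <- outcomes[outcomes$endpoint == endpoint, , drop = FALSE]
  stopIfNot(nrow(x) >= 1,
            sprintf("no outcome records for endpoint %s", endpoint))
  stopIfNot(all(x$category %in% c("Up", "Stable", "Down")),
            "categories must be Up/Stable/Down")
  responders <- if (endpoint == "diet") {
    sum(x$category == "Up")
  } else {
    sum(x$category %in% c("Stable", "Down"))
  }
  pct(responders, nrow(x), 0)
}

#' Fraction of logistic curves whose ppc exceeds the GI50
#'
#' Among logistic classifications carrying a GI50 and a known ppc, the
#' percentage for which the peak plasma concentration is strictly greater
#' than the GI50 (i.e. a growth-inhibitory concentration is clinically
#' achievable).
#'
#' @param curves data.frame with columns \code{pattern}, \code{gi50},
#'   \code{ppc}.
#' @return percentage (integer-rounded).
#' @export
ppcExceedanceFraction <- function(curves) {
  el <- curves$pattern == "logistic" & !is.na(curves$gi50) &
    !is.na(curves$ppc)
  if (!any(el)) {
    stop("undefined rate: no logistic curves with GI50 and ppc",
         call. = FALSE)
  }
  pct(sum(curves$ppc[el] > curves$gi50[el]), sum(el), 0)
}

#' Rank frequency and mean rank per drug
#'
#' Counts how often each drug attained each within-specimen rank across a
#' set of specimen rankings, plus the arithmetic mean of its 1-based
#' ranks. Resistant and unevaluable assays are excluded from the mean.
#'
#' @param rankings list of \linkS4class{SensitivityRanking}.
#' @return data.frame with columns \code{drug}, \code{nRanked},
#'   \code{meanRank} and \code{rank<k>} count columns.
#' @export
rankFrequency <- function(rankings) {
  rows <- do.call(rbind, lapply(rankings, function(r) r@ranked))
  if (is.null(rows) || nrow(rows) == 0) {
    return(data.frame(drug = character(), nRanked = integer(),
                      meanRank = numeric()))
  }
  max_rank <- max(rows$rank)
  drugs <- sort(unique(rows$drug))
  out <- data.frame(drug = drugs,
                    nRanked = as.integer(table(factor(rows$drug, drugs))),
                    meanRank = vapply(drugs, function(d) {
                      mean(rows$rank[rows$drug == d])
                    }, numeric(1)))
  for (k in seq_len(max_rank)) {
    out[[paste0("rank", k)]] <- vapply(drugs, function(d) {
      sum(rows$drug == d & rows$rank == k)
    }, integer(1))
  }
  rownames(out) <- NULL
  out
}

#' Flatten classifications to a plain table
#'
#' @param classifications list of \linkS4class{CurveClassification}.
#' @param panel optional panel for a \code{ppc} column.
#' @return data.frame with columns \code{specimen_id}, \code{drug},
#'   \code{pattern}, \code{informative}, \code{gi50}, \code{gi50_in_range},
#'   \code{r2_adj}, \code{aicc} and (if panel given) \code{ppc}.
#' @export
classificationTable <- function(classifications, panel = NULL) {
  df <- do.call(rbind, lapply(classifications, function(cl) {
    f <- cl@bestFit
    data.frame(specimen_id = cl@specimenId, drug = cl@drug,
               pattern = cl@pattern, informative = cl@informative,
               gi50 = cl@gi50, gi50_in_range = cl@gi50InRange,
               r2_adj = if (is.null(f)) NA_real_ else f@r2Adj,
               aicc = if (is.null(f)) NA_real_ else f@aicc,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(panel)) {
    df$ppc <- vapply(df$drug, panelPpc, numeric(1), panel = panel)
  }
  rownames(df) <- NULL
  df
}

# ---- shipped reference tables (printed cohort counts as inputs) --------

refPath <- function(file) {
  system.file("extdata", file, package = "chemoRank", mustWork = TRUE)
}

#' Reference specimen cohort (43 specimens)
#'
#' Specimen records reconstructed from the published attrition structure of
#' the 43-specimen gastric cancer cohort: 22 ascites / 21 solid sources, 34
#' with sufficient cells, 29 analyzed; exclusions are low viability (one
#' per source) and fungal (2) / bacterial (1) contamination among solid
#' tumors. Identifiers are synthetic (ASC-01.., SOL-01..); only the
#' marginal counts are data.
#'
#' @return specimen records data.frame (see \code{\link{informativeRate}}).
#' @export
referenceCohort <- function() {
  att <- read.delim(refPath("reference_attrition.tsv"),
                    stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(att)), function(i) {
    a <- att[i, ]
    prefix <- if (a$source == "ascites") "ASC" else "SOL"
    n <- a$n_total
    reasons <- c(rep("none", a$n_analyzed),
                 rep("low_viability", a$excl_low_viability),
                 rep("fungal_contamination", a$excl_fungal),
                 rep("bacterial_contamination", a$excl_bacterial),
                 rep("none", n - a$n_sufficient))
    data.frame(
      specimen_id = sprintf("%s-%02d", prefix, seq_len(n)),
      source = a$source,
      cells_sufficient = seq_len(n) <= a$n_sufficient,
      exclusion_reason = reasons,
      analyzed = seq_len(n) <= a$n_analyzed,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Reference curve-type counts (193 curves)
#'
#' The published per-drug curve-type frequency table: 19 assayed drugs and
#' combinations by the six patterns, totalling 193 curves (93 logistic, 33
#' hyperbolic, 9 straight, 2 exponential, 13 linear, 43 noise-dominant).
#'
#' @return data.frame with column \code{drug} and one count column per
#'   pattern.
#' @export
referenceCurveCounts <- function() {
  df <- read.delim(refPath("reference_curve_counts.tsv"),
                   stringsAsFactors = FALSE, check.names = FALSE)
  stopIfNot(all(c("drug", CURVE_PATTERNS) %in% names(df)),
            "malformed reference curve count table")
  df
}

#' Expand curve-type counts into one row per curve
#'
#' Specimen identifiers are assigned round-robin over the analyzed
#' specimens of the reference cohort so that the ascites/solid curve
#' totals (110 from 15 cases, 83 from 14 cases) hold; the assignment of
#' individual curves to specimens is otherwise synthetic.
#'
#' @param counts count table (default \code{\link{referenceCurveCounts}}).
#' @param records specimen records (default \code{\link{referenceCohort}}).
#' @return classification table with columns \code{specimen_id},
#'   \code{drug}, \code{pattern}.
#' @export
referenceClassifications <- function(counts = referenceCurveCounts(),
                                     records = referenceCohort()) {
  long <- do.call(rbind, lapply(CURVE_PATTERNS, function(p) {
    n <- counts[[p]]
    data.frame(drug = rep(counts$drug, n),
               pattern = rep(p, sum(n)), stringsAsFactors = FALSE)
  }))
  att <- read.delim(refPath("reference_attrition.tsv"),
                    stringsAsFactors = FALSE)
  sid <- unlist(lapply(seq_len(nrow(att)), function(i) {
    a <- att[i, ]
    ids <- records$specimen_id[records$source == a$source & records$analyzed]
    rep_len(ids, a$n_curves)
  }))
  stopIfNot(length(sid) == nrow(long),
            "curve totals disagree with attrition table")
  data.frame(specimen_id = sid, long, stringsAsFactors = FALSE)
}

#' Reference outcome records (13 ascites cases)
#'
#' Up/Stable/Down outcome counts for the 13 chemotherapy-treated ascites
#' cases, expanded to one record per case and endpoint: tumor markers CEA
#' and CA19-9, ascites volume, and dietary intake.
#'
#' @return outcome records data.frame (columns \code{specimen_id},
#'   \code{endpoint}, \code{category}).
#' @export
referenceOutcomes <- function() {
  cnt <- read.delim(refPath("reference_outcomes.tsv"),
                    stringsAsFactors = FALSE, check.names = FALSE)
  do.call(rbind, lapply(seq_len(nrow(cnt)), function(i) {
    r <- cnt[i, ]
    n <- r$Up + r$Stable + r$Down
    data.frame(specimen_id = sprintf("CASE-%02d", seq_len(n)),
               endpoint = r$endpoint,
               category = rep(c("Up", "Stable", "Down"),
                              c(r$Up, r$Stable, r$Down)),
               stringsAsFactors = FALSE)
  }))
}

#' Cohort summary bundle
#'
#' Aggregates specimen records, classified curves and outcome records into
#' the cohort-level statistics: informative rates, the curve-type
#' frequency table, drugs-per-specimen ratios per source, and responded
#' fractions per endpoint.
#'
#' @param records specimen records.
#' @param curves classification table (needs \code{specimen_id},
#'   \code{drug}, \code{pattern}; \code{gi50}/\code{ppc} enable the ppc
#'   exceedance fraction).
#' @param outcomes optional outcome records.
#' @return list of class \code{cohortSummary}.
#' @export
cohortSummary <- function(records, curves, outcomes = NULL) {
  ir <- informativeRate(records)
  freq <- curveTypeFrequency(curves)
  dps <- lapply(setNames(nm = unique(records$source)), function(s) {
    tryCatch(drugsPerSpecimen(curves, records, s), error = function(e) NA_real_)
  })
  resp <- NULL
  if (!is.null(outcomes) && nrow(outcomes)) {
    eps <- unique(outcomes$endpoint)
    resp <- setNames(vapply(eps, function(e) respondedFraction(outcomes, e),
                            numeric(1)), eps)
  }
  exceed <- if (!is.null(curves$gi50) && !is.null(curves$ppc)) {
    tryCatch(ppcExceedanceFraction(curves), error = function(e) NA_real_)
  } else {
    NA_real_
  }
  structure(list(informativeRate = ir,
                 patternFrequency = freq,
                 drugsPerSpecimen = dps,
                 respondedFraction = resp,
                 ppcExceedance = exceed),
            class = "cohortSummary")
}
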
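#' Chemosensitivity score: log margin between ppc and GI50
#'
#' \code{log10(ppc / gi50)}: positive when the peak plasma concentration
#' exceeds the GI50, i.e. when a growth-inhibitory concentration is
#' clinically achievable. The log ratio (rather than the arithmetic
#' difference) is used because panel concentrations span about five orders
#' of magnitude, making the ratio the only scale-free reading of the
#' margin.
#'
#' @param gi50 GI50 in uM (> 0).
#' @param ppc peak plasma concentration in uM (> 0).
#' @return dimensionless score.
#' @examples
#' sensitivityScore(0.0586, 5.86)  # 2: ppc is 100x the GI50
#' @export
sensitivityScore <- function(gi50, ppc) {
  stopIfNot(all(gi50 > 0), "domain error: gi50 must be positive")
  stopIfNot(all(ppc > 0), "domain error: ppc must be positive")
  log10(ppc / gi50)
}

#' Does the peak plasma concentration exceed the GI50?
#'
#' Strict comparison: a drug whose GI50 equals its ppc is not counted as
#' clinically promising.
#'
#' @inheritParams sensitivityScore
#' @return logical.
#' @export
ppcExceedsGi50 <- function(gi50, ppc) {
  stopIfNot(all(gi50 > 0), "domain error: gi50 must be positive")
  stopIfNot(all(ppc > 0), "domain error: ppc must be positive")
  ppc > gi50
}

#' Rank the drugs assayed on one specimen
#'
#' Drugs with a logistic pattern, a present GI50 and a known ppc are
#' ordered by descending \code{\link{sensitivityScore}} (ties broken by
#' smaller GI50, then lexicographic drug code). Hyperbolic drugs form the
#' resistant set. Everything else (non-informative pattern, GI50 absent,
#' ppc not determined) is unevaluable. Drugs whose ppc is below their GI50
#' are still ranked, with a negative score. GI50 values flagged as lying
#' outside the tested concentration range are ranked but marked low
#' confidence.
#'
#' @param classifications list of \linkS4class{CurveClassification} for one
#'   specimen (one per drug).
#' @param panel panel data.frame (see \code{\link{readPanel}}) supplying
#'   ppc lookups.
#' @return a \linkS4class{SensitivityRanking}.
#' @export
rankSpecimen <- function(classifications, panel) {
  stopIfNot(length(classifications) >= 1,
            "at least one classification required")
  sids <- unique(vapply(classifications, function(x) x@specimenId,
                        character(1)))
  stopIfNot(length(sids) == 1,
            "all classifications must be from one specimen")
  drugs <- vapply(classifications, function(x) x@drug, character(1))
  if (anyDuplicated(drugs)) {
    stop("duplicate-entry error: a drug appears more than once for this specimen",
         call. = FALSE)
  }

  ranked <- data.frame(drug = character(), gi50 = numeric(),
                       ppc = numeric(), score = numeric(),
                       rank = integer(), lowConfidence = logical(),
                       stringsAsFactors = FALSE)
  resistant <- character()
  unev <- data.frame(drug = character(), reason = character(),
                     gi50 = numeric(), stringsAsFactors = FALSE)

  for (cl in classifications) {
    if (cl@pattern == "hyperbolic") {
      resistant <- c(resistant, cl@drug)
    } else if (cl@pattern == "logistic" && !is.na(cl@gi50)) {
      ppc <- panelPpc(panel, cl@drug)
      if (is.na(ppc)) {
        unev <- rbind(unev, data.frame(drug = cl@drug, reason = "ppc_unknown",
                                       gi50 = cl@gi50))
      } else {
        ranked <- rbind(ranked, data.frame(
          drug = cl@drug, gi50 = cl@gi50, ppc = ppc,
          score = sensitivityScore(cl@gi50, ppc), rank = NA_integer_,
          lowConfidence = !isTRUE(cl@gi50InRange)))
      }
    } else {
      reason <- if (cl@pattern == "logistic") "gi50_absent" else "uninformative_pattern"
      unev <- rbind(unev, data.frame(drug = cl@drug, reason = reason,
                                     gi50 = NA_real_))
    }
  }

  if (nrow(ranked)) {
    o <- order(-ranked$score, ranked$gi50, ranked$drug, method = "radix")
    ranked <- ranked[o, , drop = FALSE]
    ranked$rank <- seq_len(nrow(ranked))
    rownames(ranked) <- NULL
  }
  resistant <- sort(resistant)
  if (nrow(unev)) {
    unev <- unev[order(unev$drug), , drop = FALSE]
    rownames(unev) <- NULL
  }
  new("SensitivityRanking", specimenId = sids,
      ranked = ranked, resistant = resistant, unevaluable = unev)
}

#' GI50 fold change between two assays of the same drug
#'
#' Used to compare chemosensitivity tests taken before and after a course
#' of chemotherapy on the same patient; a fold increase of five or more is
#' read as an acquired-resistance shift. The fold is absent when either
#' assay lacks a GI50 (for example a hyperbolic, already-resistant curve);
#' in that case the post-assay resistance flag is carried through.
#'
#' @param pre,post \linkS4class{CurveClassification} objects for the same
#'   drug.
#' @return list with \code{fold} (post GI50 / pre GI50, or NA),
#'   \code{resistantPre}, \code{resistantPost} (logicals).
#' @export
gi50FoldChange <- function(pre, post) {
  if (!identical(pre@drug, post@drug)) {
    stop("comparison error: classifications refer to different drugs",
         call. = FALSE)
  }
  fold <- if (!is.na(pre@gi50) && !is.na(post@gi50)) {
    post@gi50 / pre@gi50
  } else {
    NA_real_
  }
  list(fold = fold,
       resistantPre = pre@resistant,
       resistantPost = post@resistant)
}

# fold increase read as a resistance shift in pre/post comparisons
foldResistanceThreshold <- 5
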
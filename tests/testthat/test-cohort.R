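test_that("informative rates reproduce the cohort attrition arithmetic", {
  rec <- referenceCohort()
  expect_equal(nrow(rec), 43)
  expect_equal(sum(rec$cells_sufficient), 34)
  expect_equal(sum(rec$analyzed), 29)
  ir <- informativeRate(rec)
  expect_equal(ir$overall, 67.4)
  expect_equal(ir$sufficient, 85.3)

  none <- data.frame(specimen_id = letters[1:10], source = "ascites",
                     cells_sufficient = TRUE, exclusion_reason = "low_viability",
                     analyzed = FALSE)
  expect_equal(informativeRate(none), list(overall = 0, sufficient = 0))
  all_in <- transform(none, exclusion_reason = "none", analyzed = TRUE)
  expect_equal(informativeRate(all_in), list(overall = 100, sufficient = 100))
})

test_that("curve-type frequencies reproduce the published table arithmetic", {
  curves <- referenceClassifications()
  expect_equal(nrow(curves), 193)
  freq <- curveTypeFrequency(curves)
  expect_equal(unname(freq$totals),
               c(93, 33, 9, 2, 13, 43))
  expect_equal(freq$fractions[["logistic"]], 48.2)
  expect_equal(freq$informativeFraction, 65.3)  # 126/193
  # within-pattern per-drug column fractions, e.g. CIS hyperbolic 11/33
  expect_equal(freq$columnFractions["CIS", "hyperbolic"], 33.3)
  expect_equal(freq$columnFractions["PXL", "logistic"], 23.7)
  # column fractions sum to 100 within rounding
  for (p in colnames(freq$counts)) {
    if (freq$totals[[p]] > 0) {
      expect_lt(abs(sum(freq$columnFractions[, p]) - 100), 0.31)
    }
  }
  expect_lt(abs(sum(freq$fractions) - 100), 0.31)
})

test_that("degenerate frequency tables behave", {
  one <- data.frame(specimen_id = "S", drug = "PXL", pattern = "logistic")
  expect_equal(curveTypeFrequency(one)$fractions[["logistic"]], 100)
  eq <- data.frame(specimen_id = "S", drug = "PXL",
                   pattern = c("logistic", "hyperbolic", "straight",
                               "exponential", "linear", "noise_dominant"))
  expect_true(all(curveTypeFrequency(eq)$fractions == 16.7))
})

test_that("drugs per specimen reproduces the per-source ratios", {
  rec <- referenceCohort()
  curves <- referenceClassifications()
  expect_equal(drugsPerSpecimen(curves, rec, "ascites"), 7.3)  # 110/15
  expect_equal(drugsPerSpecimen(curves, rec, "solid"), 5.9)   # 83/14
  single <- data.frame(specimen_id = "X", source = "ascites",
                       cells_sufficient = TRUE, exclusion_reason = "none",
                       analyzed = TRUE)
  four <- data.frame(specimen_id = rep("X", 4), drug = letters[1:4],
                     pattern = "logistic")
  expect_equal(drugsPerSpecimen(four, single), 4.0)
  expect_error(drugsPerSpecimen(curves, rec[!rec$analyzed, ]),
               "undefined rate")
})

test_that("marker transitions categorize by the upper limit of normal", {
  expect_equal(categorizeMarker(3, 8, uln = 5)$category, "Up")
  expect_equal(categorizeMarker(8, 4, uln = 5)$category, "Down")
  expect_equal(categorizeMarker(2, 3, uln = 5)$category, "Stable")
  # boundary: exactly at the limit counts as within range
  expect_equal(categorizeMarker(5, 5, uln = 5)$category, "Stable")
  # both above range: Stable with the audit flag
  above <- categorizeMarker(8, 9, uln = 5)
  expect_equal(above$category, "Stable")
  expect_true(above$aboveRange)
  expect_false(categorizeMarker(3, 8, uln = 5)$aboveRange)
  expect_error(categorizeMarker(3, 8), "configuration error")
  expect_error(categorizeMarker(3, 8, uln = -1), "configuration error")
})

test_that("responded fractions reproduce the outcome table", {
  oc <- referenceOutcomes()
  expect_equal(respondedFraction(oc, "CEA"), 54)            # 7/13
  expect_equal(respondedFraction(oc, "CA19-9"), 85)         # 11/13
  expect_equal(respondedFraction(oc, "ascites_volume"), 85) # 11/13
  expect_equal(respondedFraction(oc, "diet"), 62)           # 8/13
  expect_error(respondedFraction(oc, "weight"), "configuration error")

  all_down <- data.frame(specimen_id = 1:5, endpoint = "CEA",
                         category = "Down")
  expect_equal(respondedFraction(all_down, "CEA"), 100)

  # marker responded + Up fractions complement to 100 within rounding
  for (ep in c("CEA", "CA19-9", "ascites_volume")) {
    x <- oc[oc$endpoint == ep, ]
    up <- chemoRank:::roundHalfUp(100 * mean(x$category == "Up"))
    expect_lt(abs(respondedFraction(oc, ep) + up - 100), 1.01)
  }
})

test_that("ppc exceedance fraction counts logistic curves with known ppc", {
  mk <- function(n, exceed) {
    data.frame(pattern = "logistic", gi50 = 1,
               ppc = ifelse(seq_len(n) <= exceed, 2, 0.5))
  }
  expect_equal(ppcExceedanceFraction(mk(93, 81)), 87)
  expect_equal(ppcExceedanceFraction(mk(10, 10)), 100)
  expect_equal(ppcExceedanceFraction(mk(10, 0)), 0)
  # non-logistic and missing values are excluded from the denominator
  x <- rbind(mk(4, 2),
             data.frame(pattern = "hyperbolic", gi50 = NA, ppc = 2),
             data.frame(pattern = "logistic", gi50 = NA, ppc = 2))
  expect_equal(ppcExceedanceFraction(x), 50)
  expect_error(ppcExceedanceFraction(x[5:6, ]), "undefined rate")
})

test_that("aggregations are invariant to record order", {
  set.seed(8)
  rec <- referenceCohort()
  curves <- referenceClassifications()
  oc <- referenceOutcomes()
  rec2 <- rec[sample(nrow(rec)), ]
  curves2 <- curves[sample(nrow(curves)), ]
  oc2 <- oc[sample(nrow(oc)), ]
  expect_equal(informativeRate(rec2), informativeRate(rec))
  expect_equal(curveTypeFrequency(curves2)$totals,
               curveTypeFrequency(curves)$totals)
  expect_equal(drugsPerSpecimen(curves2, rec2, "ascites"),
               drugsPerSpecimen(curves, rec, "ascites"))
  expect_equal(respondedFraction(oc2, "CEA"), respondedFraction(oc, "CEA"))
})

test_that("rank frequency reports mean rank over ranked assays only", {
  panel <- defaultPanel()
  r1 <- rankSpecimen(list(makeClassification("PXL", "logistic", 0.05, TRUE),
                          makeClassification("DTX", "logistic", 0.5, TRUE)),
                     panel)
  r2 <- rankSpecimen(list(makeClassification("PXL", "logistic", 0.01, TRUE,
                                             specimen = "GC-002"),
                          makeClassification("CIS", "hyperbolic",
                                             specimen = "GC-002")),
                     panel)
  rf <- rankFrequency(list(r1, r2))
  pxl <- rf[rf$drug == "PXL", ]
  expect_equal(pxl$nRanked, 2L)
  expect_equal(pxl$meanRank, 1)      # rank 1 in both specimens
  expect_equal(pxl$rank1, 2L)
  expect_false("CIS" %in% rf$drug)   # resistant assays excluded
})

test_that("cohort summary bundles the reference statistics", {
  cs <- cohortSummary(referenceCohort(), referenceClassifications(),
                      referenceOutcomes())
  expect_equal(cs$informativeRate$overall, 67.4)
  expect_equal(cs$drugsPerSpecimen$ascites, 7.3)
  expect_equal(unname(cs$respondedFraction["diet"]), 62)
  expect_true(is.na(cs$ppcExceedance))  # no per-curve GI50 in printed counts
})
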
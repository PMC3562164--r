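test_that("sensitivity score is the log10 margin between ppc and GI50", {
  expect_equal(sensitivityScore(5, 5), 0)
  expect_equal(sensitivityScore(0.0586, 5.86), 2)   # ppc 100x the GI50
  expect_equal(sensitivityScore(10 * 8.33, 8.33), -1)
  expect_error(sensitivityScore(-1, 5), "domain error")
  expect_error(sensitivityScore(1, 0), "domain error")
})

test_that("ppc exceedance is strict and coincides with a positive score", {
  expect_true(ppcExceedsGi50(2, 8.33))     # cisplatin ppc 8.33 uM
  expect_false(ppcExceedsGi50(8.33, 8.33)) # boundary: not counted
  expect_false(ppcExceedsGi50(20, 8.33))
  set.seed(5)
  g <- 10^runif(200, -3, 3)
  p <- 10^runif(200, -3, 3)
  expect_identical(ppcExceedsGi50(g, p), sensitivityScore(g, p) > 0)
})

test_that("score is strictly monotone in both arguments", {
  g <- sort(10^runif(50, -2, 2))
  expect_true(all(diff(sensitivityScore(g, 5)) < 0))
  p <- sort(10^runif(50, -2, 2))
  expect_true(all(diff(sensitivityScore(0.3, p)) > 0))
})

test_that("drugs are ranked by descending score with the documented tie-breaks", {
  panel <- defaultPanel()
  # PXL gi50 chosen for score 2, DTX for score 1 -> PXL first
  cls <- list(makeClassification("DTX", "logistic", 0.232, TRUE),
              makeClassification("PXL", "logistic", 0.0586, TRUE))
  r <- rankSpecimen(cls, panel)
  rk <- rankedDrugs(r)
  expect_equal(rk$drug, c("PXL", "DTX"))
  expect_equal(rk$rank, 1:2)
  expect_equal(rk$score, c(2, 1))

  # singleton gets rank 1
  r1 <- rankSpecimen(cls[2], panel)
  expect_equal(rankedDrugs(r1)$rank, 1L)

  # equal scores: smaller GI50 wins, in either input order
  pan <- data.frame(abbreviation = c("AAA", "BBB"), name = c("a", "b"),
                    starting_concentration_uM = c(10, 10),
                    ppc_uM = c(10, 20), components = c("AAA", "BBB"))
  tie <- list(makeClassification("AAA", "logistic", 1, TRUE),
              makeClassification("BBB", "logistic", 2, TRUE))
  for (ord in list(1:2, 2:1)) {
    rk <- rankedDrugs(rankSpecimen(tie[ord], pan))
    expect_equal(rk$score, c(1, 1))
    expect_equal(rk$drug, c("AAA", "BBB"))  # gi50 1 uM ranks first
  }
})

test_that("every drug lands in exactly one compartment and order is irrelevant", {
  panel <- defaultPanel()
  cls <- list(
    makeClassification("PXL", "logistic", 0.05, TRUE),
    makeClassification("CIS", "hyperbolic"),
    makeClassification("CPT", "logistic", 1.2, TRUE),  # ppc N.D.
    makeClassification("5FU", "noise_dominant")
  )
  ref <- rankSpecimen(cls, panel)
  expect_equal(rankedDrugs(ref)$drug, "PXL")
  expect_equal(resistantDrugs(ref), "CIS")
  unev <- unevaluableDrugs(ref)
  expect_setequal(unev$drug, c("CPT", "5FU"))
  expect_equal(unev$reason[unev$drug == "CPT"], "ppc_unknown")
  expect_equal(unev$gi50[unev$drug == "CPT"], 1.2)  # GI50 still reported
  expect_equal(unev$reason[unev$drug == "5FU"], "uninformative_pattern")
  all_drugs <- c(rankedDrugs(ref)$drug, resistantDrugs(ref), unev$drug)
  expect_setequal(all_drugs, vapply(cls, drugCode, character(1)))
  expect_equal(anyDuplicated(all_drugs), 0L)

  # permutation invariance over all 24 orderings
  perms <- list(); for (a in 1:4) for (b in setdiff(1:4, a))
    for (cc in setdiff(1:4, c(a, b)))
      perms[[length(perms) + 1]] <- c(a, b, cc, setdiff(1:4, c(a, b, cc)))
  for (p in perms) {
    rp <- rankSpecimen(cls[p], panel)
    expect_identical(rankedDrugs(rp), rankedDrugs(ref))
    expect_identical(resistantDrugs(rp), resistantDrugs(ref))
    expect_identical(unevaluableDrugs(rp), unevaluableDrugs(ref))
  }
})

test_that("negative-score and out-of-range GI50 drugs are ranked but flagged", {
  panel <- defaultPanel()
  cls <- list(makeClassification("PXL", "logistic", 60, TRUE),    # ppc < gi50
              makeClassification("DTX", "logistic", 300, FALSE))  # extrapolated
  rk <- rankedDrugs(rankSpecimen(cls, panel))
  expect_equal(nrow(rk), 2)
  expect_true(all(rk$score < 0))
  expect_equal(rk$lowConfidence, c(FALSE, TRUE))
})

test_that("duplicate drugs and combinations without panel ppc are handled", {
  panel <- defaultPanel()
  dup <- list(makeClassification("PXL", "logistic", 0.1, TRUE),
              makeClassification("PXL", "hyperbolic"))
  expect_error(rankSpecimen(dup, panel), "duplicate-entry")
  combo <- list(makeClassification("CIS+5FU", "logistic", 3, TRUE))
  r <- rankSpecimen(combo, panel)
  expect_equal(unevaluableDrugs(r)$reason, "ppc_unknown")
})

test_that("GI50 fold change compares pre/post assays of one drug", {
  pre <- makeClassification("PXL", "logistic", 0.5, TRUE)
  post <- makeClassification("PXL", "logistic", 2.6, TRUE)
  fc <- gi50FoldChange(pre, post)
  expect_equal(fc$fold, 5.2)  # > 5: reported as a resistance shift
  expect_false(fc$resistantPre || fc$resistantPost)

  same <- gi50FoldChange(pre, pre)
  expect_equal(same$fold, 1)

  cis_pre <- makeClassification("CIS", "hyperbolic")
  cis_post <- makeClassification("CIS", "hyperbolic")
  fc2 <- gi50FoldChange(cis_pre, cis_post)
  expect_true(is.na(fc2$fold))          # no GI50 on either side
  expect_true(fc2$resistantPre && fc2$resistantPost)

  expect_error(gi50FoldChange(pre, cis_post), "comparison error")
})
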
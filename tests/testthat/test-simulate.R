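test_that("the default panel matches the published drug table", {
  panel <- defaultPanel()
  expect_equal(nrow(panel), 14)
  expect_equal(anyDuplicated(panel$abbreviation), 0L)
  expect_true(all(panel$starting_concentration_uM > 0))
  expect_equal(panel$ppc_uM[panel$abbreviation == "PXL"], 5.86)
  expect_equal(panel$ppc_uM[panel$abbreviation == "CIS"], 8.33)
  expect_equal(panel$starting_concentration_uM[panel$abbreviation == "CIS"],
               16.7)
  expect_true(is.na(panel$ppc_uM[panel$abbreviation == "CPT"]))  # N.D.
  expect_equal(panel$components[[which(panel$abbreviation == "5FU")]], "5FU")
  expect_equal(panelPpc(panel, "DTX"), 2.32)
  expect_true(is.na(panelPpc(panel, "CIS+5FU")))  # not a panel entry
})

test_that("dilution series start at the panel concentration and step 10-fold", {
  panel <- defaultPanel()
  cis <- panel[panel$abbreviation == "CIS", ]
  gs <- generateSeries(cis, "straight", params = c(level = 1),
                       config = simulationConfig(noiseSd = 0), seed = 1)
  conc <- sort(unique(gs$wells$concentration_uM[gs$wells$drug == "CIS"]),
               decreasing = TRUE)
  expect_equal(conc[1:3], c(16.7, 1.67, 0.167))
  expect_equal(length(conc), 7)
  expect_true(all(conc > 0))
  expect_equal(conc[-length(conc)] / conc[-1], rep(10, 6))
})

test_that("noiseless generation lies exactly on the model curve", {
  panel <- defaultPanel()
  par <- c(top = 1, bottom = 0.1, e = 0.7, h = 1.5)
  cfg <- simulationConfig(noiseSd = 0)
  gs <- generateSeries(panel[panel$abbreviation == "PXL", ], "logistic",
                       params = par, config = cfg, seed = 2)
  s <- normalizeViability(gs$wells)
  expect_equal(viability(s),
               logisticViab(concentrations(s), 1, 0.1, 0.7, 1.5),
               tolerance = 1e-12)
  expect_equal(controlMean(s), cfg$controlLevel)
})

test_that("generation is bit-identical under a fixed seed", {
  panel <- defaultPanel()
  g1 <- generateSeries(panel[3, ], "logistic", config = simulationConfig(),
                       seed = 42)
  g2 <- generateSeries(panel[3, ], "logistic", config = simulationConfig(),
                       seed = 42)
  expect_identical(g1$wells, g2$wells)
  expect_identical(g1$truth, g2$truth)
  c1 <- generateCohort(simulationConfig(nSpecimens = 8L, seed = 7))
  c2 <- generateCohort(simulationConfig(nSpecimens = 8L, seed = 7))
  expect_identical(c1, c2)
})

test_that("true GI50 exists iff the logistic truth brackets viability 0.5", {
  expect_equal(trueGi50("logistic", c(top = 1, bottom = 0, e = 2, h = 1)), 2)
  expect_true(is.na(trueGi50("logistic",
                             c(top = 1, bottom = 0.6, e = 2, h = 1))))
  expect_true(is.na(trueGi50("hyperbolic", c(top = 1, K = 5))))
  set.seed(12)
  cohort <- generateCohort(simulationConfig(nSpecimens = 12L, seed = 12))
  tr <- cohort$truths
  expect_true(all(is.na(tr$true_gi50_uM[tr$true_family != "logistic"])))
  expect_true(all(!is.na(tr$true_gi50_uM[tr$true_family == "logistic"])))
})

test_that("cohort structure respects attrition and configuration", {
  cfg0 <- simulationConfig(nSpecimens = 10L,
                           attrition = c(insufficient = 0, lowViability = 0,
                                         fungal = 0, bacterial = 0),
                           seed = 3)
  co <- generateCohort(cfg0)
  expect_equal(sum(co$records$analyzed), 10)

  cfg1 <- simulationConfig(nSpecimens = 10L,
                           patternMix = c(logistic = 1, hyperbolic = 0,
                                          straight = 0, exponential = 0,
                                          linear = 0, noise_dominant = 0),
                           seed = 4)
  co1 <- generateCohort(cfg1)
  expect_true(all(co1$truths$true_family == "logistic"))

  # analyzed implies cell-sufficient and unexcluded; excluded emit no wells
  co2 <- generateCohort(simulationConfig(nSpecimens = 30L, seed = 5))
  rec <- co2$records
  expect_true(all(rec$cells_sufficient[rec$analyzed]))
  expect_true(all(rec$exclusion_reason[rec$analyzed] == "none"))
  expect_true(all(co2$wells$specimen_id %in% rec$specimen_id[rec$analyzed]))

  # truth table and plate are 1:1 by (specimen, drug)
  w <- co2$wells[co2$wells$drug != "CONTROL", ]
  plate_pairs <- unique(paste(w$specimen_id, w$drug))
  truth_pairs <- paste(co2$truths$specimen_id, co2$truths$drug)
  expect_setequal(plate_pairs, truth_pairs)
  expect_equal(anyDuplicated(truth_pairs), 0L)

  expect_error(generateCohort(simulationConfig(drugsPerSpecimen = 99)),
               "configuration error")
})

test_that("empirical family proportions follow the pattern mix", {
  cfg <- simulationConfig(nSpecimens = 260L, seed = 6)
  co <- generateCohort(cfg)
  expect_gt(nrow(co$truths), 1000)
  emp <- table(factor(co$truths$true_family, names(cfg$patternMix))) /
    nrow(co$truths)
  expect_true(all(abs(emp - cfg$patternMix) < 0.03))
})

test_that("generator and classifier round-trip noiselessly", {
  panel <- defaultPanel()
  cfg <- simulationConfig(noiseSd = 0)
  set.seed(17)
  fams <- c("logistic", "hyperbolic", "straight", "exponential", "linear")
  ok <- 0; n <- 0
  for (fam in fams) {
    for (i in 1:8) {
      dr <- panel[sample.int(nrow(panel), 1), ]
      gs <- generateSeries(dr, fam, config = cfg, specimenId = "S")
      cl <- classifySeries(normalizeViability(gs$wells))
      n <- n + 1
      ok <- ok + (curvePattern(cl) == fam)
      if (fam %in% c("logistic", "straight")) {
        expect_equal(curvePattern(cl), fam)
      }
      if (fam == "logistic" && curvePattern(cl) == "logistic") {
        expect_equal(gi50(cl), gs$truth$gi50,
                     tolerance = 1e-6)
      }
    }
  }
  expect_gte(ok / n, 0.95)
})
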
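# Builders for synthetic series used across the test files.

logisticViab <- function(conc, top, bottom, e, h) {
  bottom + (top - bottom) / (1 + (conc / e)^h)
}

# exact (noise-free) series from any family's parameters
exactSeries <- function(family, params, conc = 70.3 / 10^(0:6),
                        specimen = "S1", drug = "PXL") {
  conc <- sort(conc)
  v <- chemoRank:::trueViability(family, params, conc)
  doseResponseSeries(specimen, drug, conc, v)
}

# noisy series: Gaussian viability noise per replicate, floored at 0
noisySeries <- function(family, params, sd, reps = 3,
                        conc = 70.3 / 10^(0:6),
                        specimen = "S1", drug = "PXL") {
  conc <- sort(conc)
  v <- chemoRank:::trueViability(family, params, conc)
  rv <- lapply(v, function(vi) pmax(0, vi + rnorm(reps, 0, sd)))
  doseResponseSeries(specimen, drug, conc, vapply(rv, mean, numeric(1)), rv)
}

# well table for one specimen-drug pair plus controls
makeWells <- function(specimen = "GC-001", drug = "CIS",
                      conc = c(0.167, 1.67, 16.7),
                      absorbance, control = c(0.78, 0.80, 0.82)) {
  reps <- length(absorbance) / length(conc)
  rbind(
    data.frame(specimen_id = specimen, drug = drug,
               concentration_uM = rep(conc, each = reps),
               replicate = rep(seq_len(reps), length(conc)),
               absorbance = absorbance),
    data.frame(specimen_id = specimen, drug = "CONTROL",
               concentration_uM = NA_real_,
               replicate = seq_along(control), absorbance = control)
  )
}

# bare classification object for ranking tests
makeClassification <- function(drug, pattern, gi50 = NA_real_,
                               inRange = NA, specimen = "GC-001") {
  methods::new("CurveClassification",
               specimenId = specimen, drug = drug, pattern = pattern,
               informative = pattern %in% c("logistic", "hyperbolic"),
               resistant = pattern == "hyperbolic",
               gi50 = gi50, gi50InRange = inRange, bestFit = NULL)
}
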
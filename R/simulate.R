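#' Simulation settings for synthetic assay cohorts
#'
#' Defaults emulate the study conditions of the reference cohort: 43
#' specimens with a 22:21 ascites:solid mix, 10-fold dilution series of 7
#' doses in triplicate, additive Gaussian viability noise, a pattern mix
#' equal to the published curve-type fractions (93/33/9/2/13/43 of 193),
#' and attrition probabilities from the published counts (9/43 with
#' insufficient cells; among cell-sufficient specimens 2/34 low viability,
#' 2/34 fungal and 1/34 bacterial contamination).
#'
#' @param nSpecimens number of specimens to draw.
#' @param sourceMix probability a specimen is from ascites.
#' @param drugsPerSpecimen named numeric, mean number of assayed drugs per
#'   source (draws are Poisson, clamped to 3..panel size).
#' @param nDilutions number of 10-fold dilution points (>= 3).
#' @param replicates wells per concentration.
#' @param noiseSd additive Gaussian noise SD on the viability scale.
#' @param patternMix named probabilities per pattern (must sum to 1).
#' @param attrition named probabilities: \code{insufficient} (per
#'   specimen), \code{lowViability}, \code{fungal}, \code{bacterial}
#'   (per cell-sufficient specimen, mutually exclusive).
#' @param controlLevel mean control-well absorbance (OD).
#' @param nControlWells untreated control wells per specimen.
#' @param outcomeProbs list per endpoint of Up/Stable/Down probabilities
#'   for synthetic outcome records.
#' @param seed RNG seed used by \code{\link{generateCohort}}.
#' @return list of class \code{simulationConfig}.
#' @export
simulationConfig <- function(nSpecimens = 43L,
                             sourceMix = 22 / 43,
                             drugsPerSpecimen = c(ascites = 7.3, solid = 5.9),
                             nDilutions = 7L,
                             replicates = 3L,
                             noiseSd = 0.05,
                             patternMix = c(logistic = 93, hyperbolic = 33,
                                            straight = 9, exponential = 2,
                                            linear = 13,
                                            noise_dominant = 43) / 193,
                             attrition = c(insufficient = 9 / 43,
                                           lowViability = 2 / 34,
                                           fungal = 2 / 34,
                                           bacterial = 1 / 34),
                             controlLevel = 0.8,
                             nControlWells = 6L,
                             outcomeProbs = list(
                               "CEA" = c(Up = 6, Stable = 3, Down = 4) / 13,
                               "CA19-9" = c(Up = 2, Stable = 7, Down = 4) / 13,
                               "ascites_volume" = c(Up = 2, Stable = 3, Down = 8) / 13,
                               "diet" = c(Up = 8, Stable = 0, Down = 5) / 13),
                             seed = 1L) {
  stopIfNot(nDilutions >= 3, "nDilutions must be >= 3")
  stopIfNot(noiseSd >= 0, "noiseSd must be >= 0")
  stopIfNot(abs(sum(patternMix) - 1) < 1e-8, "patternMix must sum to 1")
  stopIfNot(all(patternMix >= 0) && all(attrition >= 0) &&
              all(attrition <= 1), "probabilities must lie in [0, 1]")
  stopIfNot(all(CURVE_PATTERNS %in% names(patternMix)),
            "patternMix must name all six patterns")
  structure(list(nSpecimens = as.integer(nSpecimens), sourceMix = sourceMix,
                 drugsPerSpecimen = drugsPerSpecimen,
                 nDilutions = as.integer(nDilutions),
                 replicates = as.integer(replicates),
                 noiseSd = noiseSd, patternMix = patternMix,
                 attrition = attrition, controlLevel = controlLevel,
                 nControlWells = as.integer(nControlWells),
                 outcomeProbs = outcomeProbs, seed = seed),
            class = "simulationConfig")
}

#' Draw true curve parameters for one family
#'
#' Priors (stated so parameter-recovery tests are reproducible):
#' logistic top ~ U(0.9, 1.1), bottom ~ U(0, 0.25), log10(e) uniform over
#' the central doses (10 x min dose .. max dose / 10), hill ~ U(1, 3);
#' hyperbolic top ~ U(0.9, 1.1), log10(K) ~ U(log10 cmax, log10 2.5 cmax);
#' straight level ~ U(0.3, 1.1); exponential a ~ U(0.9, 1.1),
#' k = U(3, 8)/cmax; linear endpoints U(0.9, 1.1) down to U(0.02, 0.3)
#' across the tested decades; noise-dominant per-dose levels ~ U(0.2, 1.2).
#'
#' @param family pattern name.
#' @param conc tested concentrations (uM).
#' @return named numeric vector of natural-scale parameters (for
#'   noise_dominant, the per-dose base levels).
#' @export
drawFamilyParams <- function(family, conc) {
  cmin <- min(conc); cmax <- max(conc)
  switch(family,
    logistic = c(top = runif(1, 0.9, 1.1), bottom = runif(1, 0, 0.25),
                 e = 10^runif(1, log10(cmin * 10), log10(cmax / 10)),
                 h = runif(1, 1, 3)),
    hyperbolic = c(top = runif(1, 0.9, 1.1),
                   K = 10^runif(1, log10(cmax), log10(2.5 * cmax))),
    straight = c(level = runif(1, 0.3, 1.1)),
    exponential = c(a = runif(1, 0.9, 1.1), k = runif(1, 3, 8) / cmax),
    linear = {
      v0 <- runif(1, 0.9, 1.1)
      v1 <- runif(1, 0.02, 0.3)
      m <- (v0 - v1) / (log10(cmax) - log10(cmin))
      c(a = v0 + m * log10(cmin), m = m)
    },
    noise_dominant = setNames(runif(length(conc), 0.2, 1.2),
                              paste0("level", seq_along(conc))),
    stop(sprintf("generation error: unknown family '%s'", family),
         call. = FALSE)
  )
}

#' True GI50 implied by generating parameters
#'
#' Defined only for logistic truths whose asymptotes bracket viability 0.5.
#'
#' @param family true family.
#' @param params true parameters.
#' @return GI50 in uM, or NA.
#' @export
trueGi50 <- function(family, params) {
  if (family != "logistic") return(NA_real_)
  t <- params[["top"]]; b <- params[["bottom"]]
  if (!(b < 0.5 && t > 0.5)) return(NA_real_)
  params[["e"]] * ((t - 0.5) / (0.5 - b))^(1 / params[["h"]])
}

trueViability <- function(family, params, conc) {
  if (family == "noise_dominant") {
    as.numeric(params)
  } else {
    familyPredict(family, params, conc)
  }
}

#' Generate one synthetic specimen-drug dilution series
#'
#' Concentrations form a 10-fold dilution series from the drug's starting
#' concentration. Each well's absorbance is
#' \code{controlLevel * (model viability + N(0, noiseSd))}, floored at 0;
#' control wells use model viability 1. Deterministic given \code{seed}.
#'
#' @param drugSpec one panel row (needs \code{abbreviation} and
#'   \code{starting_concentration_uM}).
#' @param family true pattern.
#' @param params true parameters (default: drawn from the priors).
#' @param config a \code{\link{simulationConfig}}.
#' @param seed optional seed (NULL continues the current RNG stream).
#' @param specimenId identifier for the emitted wells.
#' @param includeControls emit the specimen's control wells too.
#' @return list with \code{wells} (well measurement data.frame) and
#'   \code{truth} (list: specimen_id, drug, family, params, gi50).
#' @export
generateSeries <- function(drugSpec, family, params = NULL,
                           config = simulationConfig(), seed = NULL,
                           specimenId = "S1", includeControls = TRUE) {
  stopIfNot(family %in% CURVE_PATTERNS,
            sprintf("generation error: unknown family '%s'", family))
  if (!is.null(seed)) set.seed(seed)
  conc <- drugSpec$starting_concentration_uM /
    10^(seq_len(config$nDilutions) - 1)
  if (is.null(params)) params <- drawFamilyParams(family, conc)
  v_true <- trueViability(family, params, conc)
  stopIfNot(length(v_true) == length(conc) && all(is.finite(v_true)),
            "generation error: invalid parameters for family")

  nrep <- config$replicates
  treated <- data.frame(
    specimen_id = specimenId,
    drug = drugSpec$abbreviation,
    concentration_uM = rep(conc, each = nrep),
    replicate = rep(seq_len(nrep), length(conc)),
    absorbance = pmax(0, config$controlLevel *
                        (rep(v_true, each = nrep) +
                           rnorm(length(conc) * nrep, 0, config$noiseSd))),
    stringsAsFactors = FALSE)
  wells <- treated
  if (includeControls) {
    ctrl <- data.frame(
      specimen_id = specimenId, drug = CONTROL_CODE,
      concentration_uM = NA_real_,
      replicate = seq_len(config$nControlWells),
      absorbance = pmax(0, config$controlLevel *
                          (1 + rnorm(config$nControlWells, 0,
                                     config$noiseSd))),
      stringsAsFactors = FALSE)
    wells <- rbind(wells, ctrl)
  }
  list(wells = wells,
       truth = list(specimen_id = specimenId,
                    drug = drugSpec$abbreviation,
                    family = family, params = params,
                    gi50 = trueGi50(family, params)))
}

#' Generate a synthetic specimen cohort
#'
#' Draws specimens with source and attrition, assays each analyzed
#' specimen with a per-source Poisson number of panel drugs (without
#' replacement), generates each series from a pattern drawn from the
#' pattern mix, and draws synthetic outcome records for analyzed ascites
#' specimens. Excluded specimens emit no wells. Fully deterministic given
#' \code{config$seed}.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param panel drug panel (default \code{\link{defaultPanel}}).
#' @return list with \code{wells}, \code{records} (specimen records),
#'   \code{truths} (data.frame: specimen_id, drug, true_family,
#'   true_gi50_uM, params_json), \code{outcomes}.
#' @export
generateCohort <- function(config = simulationConfig(),
                           panel = defaultPanel()) {
  max_drugs <- nrow(panel)
  mean_drugs <- config$drugsPerSpecimen
  stopIfNot(all(mean_drugs <= max_drugs),
            "configuration error: drugsPerSpecimen exceeds panel size")
  set.seed(config$seed)

  wells <- list(); truths <- list(); outs <- list()
  records <- data.frame()
  for (i in seq_len(config$nSpecimens)) {
    source <- if (runif(1) < config$sourceMix) "ascites" else "solid"
    sid <- sprintf("GC-%03d", i)
    sufficient <- runif(1) >= config$attrition[["insufficient"]]
    reason <- "none"
    if (sufficient) {
      u <- runif(1)
      a <- config$attrition
      reason <- if (u < a[["lowViability"]]) {
        "low_viability"
      } else if (u < a[["lowViability"]] + a[["fungal"]]) {
        "fungal_contamination"
      } else if (u < a[["lowViability"]] + a[["fungal"]] + a[["bacterial"]]) {
        "bacterial_contamination"
      } else {
        "none"
      }
    }
    analyzed <- sufficient && reason == "none"
    records <- rbind(records, data.frame(
      specimen_id = sid, source = source, cells_sufficient = sufficient,
      exclusion_reason = reason, analyzed = analyzed,
      stringsAsFactors = FALSE))
    if (!analyzed) next

    mu <- if (length(mean_drugs) > 1) mean_drugs[[source]] else mean_drugs[[1]]
    n_drugs <- min(max(rpois(1, mu), 3L), max_drugs)
    drug_idx <- sample.int(max_drugs, n_drugs)
    ctrl <- data.frame(
      specimen_id = sid, drug = CONTROL_CODE, concentration_uM = NA_real_,
      replicate = seq_len(config$nControlWells),
      absorbance = pmax(0, config$controlLevel *
                          (1 + rnorm(config$nControlWells, 0,
                                     config$noiseSd))),
      stringsAsFactors = FALSE)
    wells[[length(wells) + 1]] <- ctrl
    for (j in drug_idx) {
      fam <- sample(names(config$patternMix), 1, prob = config$patternMix)
      gs <- generateSeries(panel[j, ], fam, params = NULL, config = config,
                           seed = NULL, specimenId = sid,
                           includeControls = FALSE)
      wells[[length(wells) + 1]] <- gs$wells
      truths[[length(truths) + 1]] <- data.frame(
        specimen_id = sid, drug = gs$truth$drug,
        true_family = fam,
        true_gi50_uM = gs$truth$gi50,
        params_json = as.character(jsonlite::toJSON(as.list(gs$truth$params),
                                                    auto_unbox = TRUE,
                                                    digits = NA)),
        stringsAsFactors = FALSE)
    }
    if (source == "ascites") {
      for (ep in names(config$outcomeProbs)) {
        pr <- config$outcomeProbs[[ep]]
        outs[[length(outs) + 1]] <- data.frame(
          specimen_id = sid, endpoint = ep,
          category = sample(names(pr), 1, prob = pr),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(wells = if (length(wells)) do.call(rbind, wells) else data.frame(),
       records = records,
       truths = if (length(truths)) do.call(rbind, truths) else data.frame(),
       outcomes = if (length(outs)) do.call(rbind, outs) else data.frame())
}
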
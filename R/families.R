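# Curve family definitions.
#
# Each family is a minimal parametric form reproducing one of the named
# dose-response shapes; all are identifiable from <= 8 dose points:
#   logistic     v(c) = b + (t - b) / (1 + (c/e)^h)        (4PL, decreasing)
#   hyperbolic   v(c) = t * K / (K + c), K >= 2nd-highest dose
#                (flat across the practical range, decline only at the top)
#   straight     v(c) = a
#   exponential  v(c) = a * exp(-k c)
#   linear       v(c) = max(0, a - m * log10(c))
#
# Optimization happens on a transformed scale (log10 for the concentration-
# like parameters e, K, k) inside box bounds; parameters are stored on the
# natural scale with concentrations in uM.

familyPredict <- function(family, par, conc) {
  switch(family,
    logistic = {
      t <- par[["top"]]; b <- par[["bottom"]]
      e <- par[["e"]]; h <- par[["h"]]
      b + (t - b) / (1 + exp(h * (log(conc) - log(e))))
    },
    hyperbolic = {
      t <- par[["top"]]; K <- par[["K"]]
      t * K / (K + conc)
    },
    straight = rep(par[["level"]], length(conc)),
    exponential = par[["a"]] * exp(-par[["k"]] * conc),
    linear = pmax(0, par[["a"]] - par[["m"]] * log10(conc)),
    stop(sprintf("unknown family '%s'", family), call. = FALSE)
  )
}

familyNPar <- c(logistic = 4L, hyperbolic = 2L, straight = 1L,
                exponential = 2L, linear = 2L)

# deterministic tie-break order among families with equal AICc and equal
# parameter count
familyOrder <- c(logistic = 1L, hyperbolic = 2L, straight = 3L,
                 exponential = 4L, linear = 5L)

familyParNames <- list(
  logistic = c("top", "bottom", "e", "h"),
  hyperbolic = c("top", "K"),
  straight = "level",
  exponential = c("a", "k"),
  linear = c("a", "m")
)

# transformed-scale parameterization -------------------------------------

familyToOpt <- function(family, par) {
  switch(family,
    logistic = c(par[["top"]], par[["bottom"]], log10(par[["e"]]), par[["h"]]),
    hyperbolic = c(par[["top"]], log10(par[["K"]])),
    exponential = c(par[["a"]], log10(par[["k"]])),
    linear = c(par[["a"]], par[["m"]]),
    stop("no optimization for this family")
  )
}

familyFromOpt <- function(family, theta) {
  par <- switch(family,
    logistic = c(theta[1], theta[2], 10^theta[3], theta[4]),
    hyperbolic = c(theta[1], 10^theta[2]),
    exponential = c(theta[1], 10^theta[2]),
    linear = theta
  )
  names(par) <- familyParNames[[family]]
  par
}

familyBounds <- function(family, conc) {
  lc <- log10(range(conc))
  c2 <- sort(conc, decreasing = TRUE)[2]  # second-highest dose
  switch(family,
    # hill slope capped at 4: with 10-fold dilution steps the transition of
    # any steeper curve falls between adjacent doses, so h is unidentified
    # upward and runs away, dragging the 0.5-crossing with it
    logistic = list(lower = c(0.1, 0, lc[1] - 2, 0.1),
                    upper = c(1.2, 1.0, lc[2] + 2, 4)),
    hyperbolic = list(lower = c(0.1, log10(c2)),
                      upper = c(1.5, lc[2] + 4)),
    exponential = list(lower = c(0.05, log10(0.01 / max(conc))),
                       upper = c(1.5, log10(50 / min(conc)))),
    linear = list(lower = c(-20, 1e-4), upper = c(20, 20))
  )
}

# fixed multi-start grid per family, deterministic in the series
familyStarts <- function(family, conc, vbar) {
  lc <- log10(range(conc))
  t0 <- min(max(max(vbar), 0.3), 1.2)
  switch(family,
    logistic = {
      es <- quantile(log10(conc), c(0.25, 0.5, 0.75), names = FALSE)
      hs <- c(0.5, 1.5, 3)
      bs <- c(0, 0.15, 0.3)
      g <- expand.grid(e = es, h = hs, b = bs)
      t(apply(g, 1, function(r) c(t0, min(r[["b"]], t0 - 0.05),
                                  r[["e"]], r[["h"]])))
    },
    hyperbolic = {
      c2 <- sort(conc, decreasing = TRUE)[2]
      Ks <- log10(c(c2 * 1.01, max(conc), 10 * max(conc)))
      ts <- c(0.8, 1.0, min(mean(vbar[-length(vbar)]) + 0.05, 1.5))
      g <- expand.grid(t = ts, K = Ks)
      as.matrix(g)
    },
    exponential = {
      ks <- log10(c(0.3, 3, 30) / max(conc))
      as <- c(0.8, 1.0, t0)
      as.matrix(expand.grid(a = as, k = ks))
    },
    linear = {
      f <- coef(lm(vbar ~ log10(conc)))
      m0 <- max(-f[[2]], 1e-3)
      a0 <- f[[1]]
      cbind(a = c(a0, a0, a0 + 0.1), m = c(m0, m0 * 2, m0 * 0.5))
    }
  )
}

# Is the observed series flat across all practical doses with a steep drop
# only at the top dose (the verbal definition of the hyperbolic pattern)?
isHyperbolicShaped <- function(series, config) {
  vbar <- series@viability
  flat <- vbar[-length(vbar)]  # all but the top dose
  mean(flat) >= config$hyperbolicFlatMean &&
    (max(flat) - min(flat)) <= config$hyperbolicFlatSpread &&
    (mean(flat) - vbar[length(vbar)]) >= config$hyperbolicTopDrop
}

# data-level shape-validity checks layered over the information criterion;
# an information criterion alone cannot encode the verbal pattern
# definitions
familyValidity <- function(family, fit, series, config) {
  conc <- series@concentrations
  par <- fit@parameters
  switch(family,
    logistic = {
      e_ok <- par[["e"]] >= min(conc) / 10 && par[["e"]] <= max(conc) * 10
      range_ok <- (par[["top"]] - par[["bottom"]]) >= config$logisticMinRange
      decline <- familyPredict(family, par, min(conc)) -
        familyPredict(family, par, max(conc))
      # a flat-then-cliff series is the resistance pattern however well a
      # steep 4PL interpolates it
      e_ok && range_ok && par[["top"]] > par[["bottom"]] &&
        decline >= config$logisticMinRange &&
        !isHyperbolicShaped(series, config)
    },
    hyperbolic = isHyperbolicShaped(series, config),
    straight = TRUE,
    exponential = {
      decline <- familyPredict(family, par, min(conc)) -
        familyPredict(family, par, max(conc))
      # a flat-then-cliff series is hyperbolic by definition, not an
      # exponential decay, however well exp(-kc) interpolates it
      decline >= config$minDecline && !isHyperbolicShaped(series, config)
    },
    linear = {
      decline <- familyPredict(family, par, min(conc)) -
        familyPredict(family, par, max(conc))
      decline >= config$minDecline
    }
  )
}
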
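# value-of-information model of annual screening

#' Construct a screening scenario
#'
#' Parameters of the annual screening decision tree: an individual has
#' FASD with prior probability `pF`; screening (cost `cS`) detects it
#' with rate `rD` (missing with `rM = 1 - rD`), or false-alarms on a
#' non-case with rate `rFA` (clearing with `rTN`).  A positive screen
#' triggers a clinical diagnostic evaluation (cost `cD`); a correct
#' detection yields the annual gain `G` of early intervention, a miss
#' incurs the annual loss `L`.  Under annual re-screening `L` is
#' expected not to exceed `G`; a scenario with `L > G` is allowed but
#' flagged with a warning.
#'
#' Default costs follow the published bounding assumptions: screening
#' under $50, clinical diagnosis under $4,000, gain at least
#' $20,000/year, loss bounded by the gain.
#'
#' @param pF prior probability of FASD.
#' @param rD detection rate (sensitivity); `rM` defaults to `1 - rD`.
#' @param rFA false alarm rate; `rTN` defaults to `1 - rFA`.
#' @param rM,rTN override the complements (must stay consistent).
#' @param cS,cD,gain,loss dollar parameters.
#' @param years screening horizon in years (default 4).
#' @return a [ScreeningScenario].
#' @examples
#' s <- screeningScenario(pF = 1, rD = 0.77, rFA = 0)
#' expectedValue(s)   # 7670
#' @export
screeningScenario <- function(pF, rD, rFA, rM = 1 - rD, rTN = 1 - rFA,
                              cS = 50, cD = 4000, gain = 20000,
                              loss = 20000, years = 4) {
  s <- new("ScreeningScenario", pF = pF, rD = rD, rM = rM, rFA = rFA,
           rTN = rTN, cS = cS, cD = cD, gain = gain, loss = loss,
           years = years)
  if (loss > gain)
    warning("loss exceeds gain; annual re-screening assumes L <= G")
  s
}

#' @describeIn expectedValue the analytic expected value
#'   `rD*pF*(G - cD - cS) - rFA*(1-pF)*(cD + cS) - rTN*(1-pF)*cS -
#'   rM*pF*(L + cS)` in dollars per screened individual per year.
#' @export
setMethod("expectedValue", "ScreeningScenario", function(scenario) {
  validObject(scenario)
  with(list(s = scenario),
       s@rD * s@pF * (s@gain - s@cD - s@cS) -
         s@rFA * (1 - s@pF) * (s@cD + s@cS) -
         s@rTN * (1 - s@pF) * s@cS -
         s@rM * s@pF * (s@loss + s@cS))
})

#' Monte-Carlo evaluation of the screening decision tree
#'
#' Simulates the decision tree draw by draw (FASD status, then the
#' screen outcome) and averages the realized values; an independent
#' cross-check of the analytic [expectedValue()].
#'
#' @param scenario a [ScreeningScenario].
#' @param nDraws number of simulated individuals.
#' @param seed RNG seed.
#' @return list: `ev` (mean realized value), `se` (standard error).
#' @export
simulateExpectedValue <- function(scenario, nDraws = 1e6, seed = 1L) {
  validObject(scenario)
  set.seed(as.integer(seed))
  s <- scenario
  fasd <- runif(nDraws) < s@pF
  u <- runif(nDraws)
  value <- numeric(nDraws)
  value[fasd] <- ifelse(u[fasd] < s@rD,
                        s@gain - s@cD - s@cS,
                        -(s@loss + s@cS))
  value[!fasd] <- ifelse(u[!fasd] < s@rFA, -(s@cD + s@cS), -s@cS)
  list(ev = mean(value), se = sd(value) / sqrt(nDraws))
}

#' Expected savings over a multi-year annual screening horizon
#'
#' An individual with FASD missed in one year is re-screened the next,
#' so the expected per-year value accumulates geometrically:
#' `ev * sum_{k=0}^{years-1} rM^k`.  Reports truncate to whole dollars
#' (see [wholeDollars()]); this function returns the exact value.
#'
#' @param evPerYear expected value per year (dollars).
#' @param rM per-screen miss rate, in `[0, 1)`.
#' @param years horizon, at least 1.
#' @return expected savings in dollars.
#' @examples
#' wholeDollars(multiYearSavings(7670, 0.23, 4))   # 9933
#' @export
multiYearSavings <- function(evPerYear, rM, years) {
  if (rM < 0 || rM >= 1)
    stop("rM must lie in [0, 1): a miss rate of 1 never detects")
  stopifnot(years >= 1)
  evPerYear * sum(rM^(seq_len(years) - 1))
}

#' Probability of missing an affected individual every year
#'
#' @param rM per-screen miss rate in \[0, 1\].
#' @param years horizon.
#' @return `rM ^ years`.
#' @examples
#' cumulativeMissProbability(0.23, 4)   # 0.00279841 < 0.003
#' @export
cumulativeMissProbability <- function(rM, years) {
  stopifnot(rM >= 0, rM <= 1, years >= 1)
  rM^years
}

#' Expected cohort-level savings
#'
#' @param scenario a [ScreeningScenario].
#' @param nScreened number of screened individuals.
#' @return `nScreened * expectedValue(scenario)` in dollars.
#' @export
cohortSavings <- function(scenario, nScreened) {
  stopifnot(nScreened >= 1)
  nScreened * expectedValue(scenario)
}

#' Risk classification at the screening threshold
#'
#' High risk when the classifier's FASD score strictly exceeds the
#' threshold (default 0.55 on the 0-1 scale).
#'
#' @param probability FASD score(s) in \[0, 1\].
#' @param threshold decision threshold.
#' @return character vector, `high_risk` / `low_risk`.
#' @examples
#' riskClassification(c(0.56, 0.55, 0))
#' @export
riskClassification <- function(probability, threshold = 0.55) {
  if (any(probability < 0 | probability > 1))
    stop("probability must lie in [0, 1]")
  ifelse(probability > threshold, "high_risk", "low_risk")
}

#' Full screening economics report
#'
#' Evaluates the per-individual expected value, the value conditional on
#' FASD (`pF = 1`), the multi-year savings accumulated over re-screens
#' of missed cases, and the cumulative miss probability.
#'
#' @param scenario a [ScreeningScenario].
#' @return an [EVResult].
#' @export
screeningEconomics <- function(scenario) {
  ev <- expectedValue(scenario)
  sF <- scenario
  sF@pF <- 1
  evFASD <- expectedValue(sF)
  # a screen that never detects (rM = 1) accumulates no savings
  savings <- if (scenario@rM < 1) {
    multiYearSavings(evFASD, scenario@rM, scenario@years)
  } else NA_real_
  new("EVResult", ev = ev, evFASD = evFASD,
      savings = savings,
      cumulativeMiss = cumulativeMissProbability(scenario@rM,
                                                 scenario@years),
      years = scenario@years)
}

setMethod("show", "ScreeningScenario", function(object) {
  cat(sprintf("ScreeningScenario: pF %.2f, rD %.4f, rFA %.4f; cS $%g, cD $%g, G $%g/yr, L $%g/yr, %g yr\n",
              object@pF, object@rD, object@rFA, object@cS, object@cD,
              object@gain, object@loss, object@years))
})

setMethod("show", "EVResult", function(object) {
  cat(sprintf("EVResult (%g-year horizon):\n", object@years))
  cat(sprintf("  EV per screened individual: $%d/yr\n",
              wholeDollars(object@ev)))
  cat(sprintf("  EV conditional on FASD:     $%d/yr\n",
              wholeDollars(object@evFASD)))
  cat(sprintf("  multi-year expected savings: $%d\n",
              wholeDollars(object@savings)))
  cat(sprintf("  cumulative miss probability: %.4f%%\n",
              100 * object@cumulativeMiss))
})
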
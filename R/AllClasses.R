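# S4 classes for the screening pipeline

#' FeatureTable: one assessment's feature matrix with participant metadata
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] wrapper holding one
#' assessment's numeric features (rows = features, columns = participants)
#' together with the group label, age, and sex of each participant.  The
#' assessment name is kept in `metadata(x)$assessment`.
#'
#' @slot .. inherits all SummarizedExperiment slots.
#' @seealso [featureTable()], [featureMatrix()], [groups()], [ages()]
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
  msg <- character(0)
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'features' is required")
  else if (!is.numeric(SummarizedExperiment::assay(object, "features")))
    msg <- c(msg, "assay 'features' must be numeric")
  cd <- SummarizedExperiment::colData(object)
  for (f in c("group", "age")) {
    if (!f %in% colnames(cd)) msg <- c(msg, sprintf("colData lacks '%s'", f))
  }
  if ("group" %in% colnames(cd) &&
      !all(as.character(cd$group) %in% c("control", "FASD")))
    msg <- c(msg, "group must be 'control' or 'FASD'")
  if (length(msg)) msg else TRUE
})

#' Specification for a synthetic multimodal cohort
#'
#' Defines group sizes, demographics, per-assessment group effect sizes,
#' missingness, and the natural-viewing trace geometry of a synthetic
#' cohort.  Constructed with [cohortSpec()]; defaults reproduce the study
#' conditions (91 FASD / 116 control, the per-assessment completion
#' pattern with 22 + 24 completing all six assessments, 70 video snippets
#' of 2-4 s sampled at 500 Hz).
#'
#' @slot nFASD,nControl group sizes.
#' @slot ageRange numeric length 2, years.
#' @slot ageMean,ageSD length-2 per-group (FASD, control) age moments.
#' @slot maleProp,rightProp length-2 per-group proportions.
#' @slot effectSizes named numeric, standardized mean group difference
#'   (Cohen's d) applied to each assessment's informative features.
#' @slot nInformative named integer, informative feature counts.
#' @slot ageSlope numeric, linear age trend (SD units per year) added to
#'   saccade features.
#' @slot missingness named list, per assessment `c(FASD, control)`
#'   completion counts.
#' @slot allComplete length-2 counts completing all six assessments.
#' @slot traceSpec list: `nSnippets`, `rateHz`, `durationRange`,
#'   `effectSnippets`, `effectChannels`.
#' @slot seed integer RNG seed.
#' @export
setClass("CohortSpec", representation(
  nFASD = "integer", nControl = "integer",
  ageRange = "numeric", ageMean = "numeric", ageSD = "numeric",
  maleProp = "numeric", rightProp = "numeric",
  effectSizes = "numeric", nInformative = "integer",
  ageSlope = "numeric",
  missingness = "list", allComplete = "integer",
  traceSpec = "list", seed = "integer"))

#' A generated synthetic cohort
#'
#' Holds the participant table, one [FeatureTable] per tabular assessment
#' (completers only), per-participant attentional eye traces for
#' natural-viewing completers, the completion mask, and the generating
#' [CohortSpec].
#'
#' @slot participants a [S4Vectors::DataFrame] (id, group, age, sex,
#'   handedness).
#' @slot assessments [S4Vectors::SimpleList] of [FeatureTable]s.
#' @slot traces [S4Vectors::SimpleList]; per natural-viewing completer, a
#'   list of snippet matrices (samples x 10 channels).
#' @slot snippetDurations numeric, seconds per snippet (shared video set).
#' @slot completion logical matrix, participants x assessments.
#' @slot spec the generating [CohortSpec].
#' @export
setClass("FASDCohort", representation(
  participants = "DataFrame", assessments = "SimpleList",
  traces = "SimpleList", snippetDurations = "numeric",
  completion = "matrix", spec = "CohortSpec"))

#' Train-referenced min-max normalization model
#'
#' Per-feature training minimum and maximum mapping training data to the
#' 0-1 range.  Constant (degenerate) features are flagged and map to 0;
#' test values outside the training range are not clipped.
#'
#' @slot features feature names, in fixed order.
#' @slot min,max named per-feature training extrema.
#' @slot degenerate logical, `max == min`.
#' @export
setClass("MinMaxModel", representation(
  features = "character", min = "numeric", max = "numeric",
  degenerate = "logical"))

setValidity("MinMaxModel", function(object) {
  if (any(object@max < object@min)) return("max < min for some feature")
  if (length(object@min) != length(object@features) ||
      length(object@max) != length(object@features))
    return("min/max length must match features")
  TRUE
})

#' Result of SVM recursive feature elimination
#'
#' @slot trajectory data.frame with one row per iteration: `iteration`,
#'   `nActive`, `looAccuracy`; active feature sets and weights are in
#'   `featureSets` / `weightSets`.
#' @slot featureSets,weightSets per-iteration active features and their
#'   contribution weights.
#' @slot selectedIteration index of the best leave-one-out accuracy
#'   (ties resolved toward fewer features).
#' @slot selectedFeatures features of the selected iteration.
#' @slot normalizedWeights selected-model weights scaled so absolute
#'   values sum to 1.
#' @slot weights,bias raw linear classifier (FASD-positive orientation).
#' @slot platt length-2 `c(A, B)` sigmoid calibration of decision values.
#' @slot cost soft-margin cost used.
#' @export
setClass("RFEResult", representation(
  trajectory = "data.frame", featureSets = "list", weightSets = "list",
  selectedIteration = "integer", selectedFeatures = "character",
  normalizedWeights = "numeric", weights = "numeric", bias = "numeric",
  platt = "numeric", cost = "numeric"))

setValidity("RFEResult", function(object) {
  s <- sum(abs(object@normalizedWeights))
  if (abs(s - 1) > 1e-10) return("normalized weights must sum to 1 in abs")
  if (!object@selectedIteration %in% seq_len(nrow(object@trajectory)))
    return("selectedIteration out of range")
  TRUE
})

#' Two-layer topographic ICA network for attentional eye traces
#'
#' Per saliency channel, two stacked TICA layers; each layer holds an
#' uncentered whitening matrix and a square orthonormal filter bank with
#' a 2x2 pooling topology on a torus map.
#'
#' @slot channels channel names, fixed order.
#' @slot layers per-channel list of two layers (`whiten`, `W`, `pool`).
#' @slot config geometry used (window length, filters, map, pooling).
#' @slot trained logical.
#' @export
setClass("TICANetwork", representation(
  channels = "character", layers = "list", config = "list",
  trained = "logical"))

setValidity("TICANetwork", function(object) {
  if (!object@trained) return(TRUE)
  for (ch in names(object@layers)) {
    for (ly in object@layers[[ch]]) {
      W <- ly$W
      dev <- norm(W %*% t(W) - diag(nrow(W)), type = "2")
      if (dev > 1e-6)
        return(sprintf("filter bank not orthonormal (channel %s, dev %.2e)",
                       ch, dev))
    }
  }
  TRUE
})

#' L1-regularized logistic regression model
#'
#' Minimizer of `sum(|w|) + C * sum(log(1 + exp(-y * (x'w + b))))` with
#' labels coded +1 (FASD) / -1 (control) internally and an optional
#' unpenalized intercept.
#'
#' @slot weights named coefficient vector (exact zeros possible).
#' @slot intercept unpenalized intercept (0 when disabled).
#' @slot hasIntercept logical.
#' @slot C loss weight of the objective.
#' @slot objective attained objective value.
#' @slot converged logical.
#' @export
setClass("L1LogRegModel", representation(
  weights = "numeric", intercept = "numeric", hasIntercept = "logical",
  C = "numeric", objective = "numeric", converged = "logical"),
  prototype(weights = numeric(0), intercept = 0, hasIntercept = TRUE,
            C = 1, objective = 0, converged = FALSE))

setValidity("L1LogRegModel", function(object) {
  if (!is.finite(object@objective)) return("objective must be finite")
  if (object@C <= 0) return("C must be > 0")
  TRUE
})

#' Result of the two-layer natural-viewing classifier
#'
#' @slot weakModels per-snippet [L1LogRegModel]s fit on all training data.
#' @slot minmax,masks per-snippet normalization models and retained-
#'   dimension masks used at test time.
#' @slot meanRep per-snippet training-mean representation (imputation).
#' @slot snippetProbs training out-of-fold snippet probabilities
#'   (participants x snippets).
#' @slot secondLayer stacking [L1LogRegModel] on the snippet
#'   probabilities.
#' @slot finalProb out-of-fold final probability per training
#'   participant.
#' @slot looAccuracy leave-one-out accuracy of the full two-layer stack.
#' @slot selectedSnippets snippet indices with non-zero second-layer
#'   coefficients.
#' @export
setClass("TwoLayerResult", representation(
  weakModels = "list", minmax = "list", masks = "list", meanRep = "list",
  snippetProbs = "matrix", secondLayer = "L1LogRegModel",
  finalProb = "numeric", looAccuracy = "numeric",
  selectedSnippets = "integer"))

setValidity("TwoLayerResult", function(object) {
  if (any(object@finalProb < 0 | object@finalProb > 1))
    return("final probabilities must lie in [0, 1]")
  TRUE
})

#' Result of probability-level fusion over an assessment subset
#'
#' @slot predictions data.frame: id, truth, probability, label, one row
#'   per held-out participant.
#' @slot subset assessments fused.
#' @slot rates the aggregate [ConfusionRates].
#' @export
setClass("FusionResult", representation(
  predictions = "data.frame", subset = "character", rates = "ANY"))

#' Ordinary least squares multilinear model
#'
#' @slot intercept,coefficients OLS estimates (minimum-norm under rank
#'   deficiency, with a warning at fit time).
#' @slot fitted fitted values.
#' @slot r2 squared correlation of response and fit.
#' @slot fstat,df1,df2,pvalue overall regression F-test.
#' @slot rank numeric rank of the design (including intercept).
#' @export
setClass("MultilinearModel", representation(
  intercept = "numeric", coefficients = "numeric", fitted = "numeric",
  r2 = "numeric", fstat = "numeric", df1 = "numeric", df2 = "numeric",
  pvalue = "numeric", rank = "integer"))

setValidity("MultilinearModel", function(object) {
  if (object@r2 < -1e-12 || object@r2 > 1 + 1e-12)
    return("r2 must lie in [0, 1]")
  TRUE
})

#' Confusion-matrix counts and rates (FASD positive)
#'
#' @slot TP,FN,FP,TN integer counts.
#' @export
setClass("ConfusionRates", representation(
  TP = "integer", FN = "integer", FP = "integer", TN = "integer"))

setValidity("ConfusionRates", function(object) {
  if (any(c(object@TP, object@FN, object@FP, object@TN) < 0))
    return("counts must be non-negative")
  TRUE
})

#' Screening scenario for the value-of-information model
#'
#' @slot pF prior probability of FASD in the screened population.
#' @slot rD,rM,rFA,rTN detection, miss, false-alarm, true-negative rates.
#' @slot cS,cD screening and clinical diagnostic cost (dollars).
#' @slot gain annual gain G from early detection (dollars/year).
#' @slot loss annual loss L from a miss (dollars/year).
#' @slot years screening horizon (years).
#' @export
setClass("ScreeningScenario", representation(
  pF = "numeric", rD = "numeric", rM = "numeric", rFA = "numeric",
  rTN = "numeric", cS = "numeric", cD = "numeric", gain = "numeric",
  loss = "numeric", years = "numeric"))

setValidity("ScreeningScenario", function(object) {
  r <- c(pF = object@pF, rD = object@rD, rM = object@rM,
         rFA = object@rFA, rTN = object@rTN)
  bad <- names(r)[r < 0 | r > 1]
  if (length(bad))
    return(sprintf("rate(s) outside [0, 1]: %s", paste(bad, collapse = ", ")))
  if (abs(object@rD + object@rM - 1) > 1e-8) return("rD + rM must equal 1")
  if (abs(object@rFA + object@rTN - 1) > 1e-8) return("rFA + rTN must equal 1")
  if (any(c(object@cS, object@cD, object@gain, object@loss) < 0))
    return("costs and gains must be non-negative")
  if (object@years < 1) return("years must be >= 1")
  TRUE
})

#' Expected-value results of the screening economics model
#'
#' @slot ev expected annual value per screened individual (dollars/year).
#' @slot evFASD expected annual value conditional on FASD (the scenario
#'   evaluated at `pF = 1`).
#' @slot savings multi-year expected savings for a detected-eventually
#'   individual with FASD (dollars).
#' @slot cumulativeMiss probability of missing an individual with FASD in
#'   every year of the horizon.
#' @slot years horizon used.
#' @export
setClass("EVResult", representation(
  ev = "numeric", evFASD = "numeric", savings = "numeric",
  cumulativeMiss = "numeric", years = "numeric"))
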
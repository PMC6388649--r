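# end-to-end orchestration on synthetic cohorts

#' Build a run configuration
#'
#' Collects everything a full pipeline run needs: the cohort
#' specification, which assessments to use, preprocessing switches, the
#' classifier settings, the screening-economics scenario parameters, and
#' the global seed.  Configurations are plain lists and can also be read
#' from YAML or JSON with [readRunConfig()].
#'
#' @param spec a [CohortSpec] (default: the study-sized cohort).
#' @param assessments assessments to analyze; subset of
#'   `prosac, antisac, mgsac, dti, psych, naturalview`.
#' @param ageCorrectAssessments assessments receiving control-referenced
#'   age correction (default: the three saccade tasks).
#' @param svmCost soft-margin cost of the RFE classifiers.
#' @param weakC,cGrid natural-viewing and fusion classifier settings.
#' @param tica [ticaConfig()] geometry for the trace representation.
#' @param pretrainParticipants size of the internally generated,
#'   held-out trace corpus used to pre-train the TICA network.
#' @param economicsSubset assessment pair driving the screening
#'   scenario's measured confusion rates.
#' @param cS,cD,gain,loss,years economics parameters (see
#'   [screeningScenario()]).
#' @param riskThreshold screening score threshold.
#' @param seed global seed; every stage derives its own stream from it.
#' @return a run configuration list.
#' @export
runConfig <- function(spec = cohortSpec(),
                      assessments = c("prosac", "antisac", "mgsac",
                                      "dti", "psych", "naturalview"),
                      ageCorrectAssessments = c("prosac", "antisac",
                                                "mgsac"),
                      svmCost = 1, weakC = 1,
                      cGrid = c(0.01, 0.1, 1, 10, 100),
                      tica = ticaConfig(),
                      pretrainParticipants = 6L,
                      economicsSubset = c("prosac", "naturalview"),
                      cS = 50, cD = 4000, gain = 20000, loss = 20000,
                      years = 4, riskThreshold = 0.55,
                      seed = 1L) {
  bad <- setdiff(assessments, .ASSESSMENTS)
  if (length(bad))
    stop("unknown assessment(s): ", paste(bad, collapse = ", "))
  list(spec = spec, assessments = assessments,
       ageCorrectAssessments = ageCorrectAssessments,
       svmCost = svmCost, weakC = weakC, cGrid = cGrid, tica = tica,
       pretrainParticipants = as.integer(pretrainParticipants),
       economicsSubset = economicsSubset,
       cS = cS, cD = cD, gain = gain, loss = loss, years = years,
       riskThreshold = riskThreshold, seed = as.integer(seed))
}

#' Read a run configuration from YAML or JSON
#'
#' Scalar overrides from the file are applied on top of [runConfig()]
#' defaults; the cohort spec fields go under a `spec:` block.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a run configuration list.
#' @export
readRunConfig <- function(path) {
  obj <- if (grepl("[.]ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  specArgs <- obj$spec %||% list()
  obj$spec <- NULL
  do.call(runConfig, c(list(spec = do.call(cohortSpec, specArgs)), obj))
}

#' Run the full screening analysis on a synthetic cohort
#'
#' Generates the cohort, reserves the participants who completed every
#' assessment as the test set (the remaining completers of each
#' assessment are its training set), trains one classifier per
#' assessment (SVM-RFE for the tabular assessments, the TICA + two-layer
#' logistic stack for natural viewing), fuses the per-assessment test
#' probabilities with the iterative train-test procedure, evaluates all
#' assessment pairs, and evaluates the screening economics at the
#' measured confusion rates of the configured screening pair.
#'
#' @param config a list from [runConfig()].
#' @param outputDir optional directory; when given, the report is
#'   written as JSON together with CSV tables.
#' @return a report list with elements `configHash`, `seed`, `chance`,
#'   `singleAssessment`, `fusion`, `subsetTable`, `economics`,
#'   `testIds`, `probabilities`, and `timestamp`.
#' @export
runFullPipeline <- function(config = runConfig(), outputDir = NULL) {
  cohort <- generateCohort(config$spec,
                           traces = "naturalview" %in% config$assessments)
  testIds <- completeAllIds(cohort)
  if (length(testIds) < 4)
    stop("stage split: too few complete-data participants for a test set")
  part <- participants(cohort)
  truthTest <- .groupFactor(part[testIds, "group"])

  single <- list()
  probs <- matrix(NA_real_, length(testIds), 0,
                  dimnames = list(testIds, NULL))
  for (a in setdiff(config$assessments, "naturalview")) {
    r <- tryCatch(
      .runSingleAssessment(cohort, a, testIds, config),
      error = function(e) stop("stage single[", a, "]: ",
                               conditionMessage(e)))
    single[[a]] <- r
    probs <- cbind(probs, r$testProb)
    colnames(probs)[ncol(probs)] <- a
  }
  if ("naturalview" %in% config$assessments) {
    r <- tryCatch(
      .runNaturalViewing(cohort, testIds, config),
      error = function(e) stop("stage naturalview: ",
                               conditionMessage(e)))
    single[["naturalview"]] <- r
    probs <- cbind(probs, naturalview = r$testProb)
  }

  fusionAll <- iterativeTrainTest(probs, truthTest, cGrid = config$cGrid)
  pairs <- evaluateSubsets(probs, truthTest,
                           assessmentPairs(colnames(probs)),
                           cGrid = config$cGrid)

  econPair <- intersect(config$economicsSubset, colnames(probs))
  econFusion <- if (length(econPair) >= 1) {
    iterativeTrainTest(probs, truthTest, subset = econPair,
                       cGrid = config$cGrid)
  } else fusionAll
  rates <- econFusion@rates
  scenario <- screeningScenario(
    pF = mean(truthTest == "FASD"),
    rD = sensitivity(rates), rFA = falseAlarmRate(rates),
    cS = config$cS, cD = config$cD, gain = config$gain,
    loss = config$loss, years = config$years)
  econ <- screeningEconomics(scenario)

  report <- list(
    configHash = .objectHash(config),
    seed = config$seed,
    cohort = list(n = nrow(part),
                  nFASD = sum(part$group == "FASD"),
                  nTest = length(testIds)),
    chance = chanceLevel(truthTest),
    singleAssessment = data.frame(
      assessment = names(single),
      trainLOO = vapply(single, `[[`, numeric(1), "trainLOO"),
      testAccuracy = vapply(single, `[[`, numeric(1), "testAccuracy"),
      row.names = NULL),
    fusion = list(subset = fusionAll@subset,
                  accuracy = accuracy(fusionAll@rates, TRUE),
                  sensitivity = sensitivity(fusionAll@rates, TRUE),
                  specificity = specificity(fusionAll@rates, TRUE)),
    subsetTable = pairs,
    economics = list(
      subset = econPair,
      sensitivity = sensitivity(rates, TRUE),
      specificity = specificity(rates, TRUE),
      accuracy = accuracy(rates, TRUE),
      ev = expectedValue(scenario),
      evFASD = econ@evFASD,
      multiYearSavings = wholeDollars(econ@savings),
      cumulativeMiss = econ@cumulativeMiss,
      cohortSavings = wholeDollars(cohortSavings(scenario,
                                                 length(testIds))),
      per1000 = wholeDollars(cohortSavings(scenario, 1000)),
      highRisk = sum(riskClassification(econFusion@predictions$probability,
                                        config$riskThreshold) ==
                       "high_risk")),
    testIds = testIds,
    probabilities = probs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  if (!is.null(outputDir)) .writeReport(report, outputDir)
  report
}

# train one tabular assessment, return train LOO / test accuracy / probs
.runSingleAssessment <- function(cohort, a, testIds, config) {
  ft <- assessmentTable(cohort, a)
  ids <- rownames(SummarizedExperiment::colData(ft))
  x <- featureMatrix(ft)
  rownames(x) <- ids
  if (a == "dti") x <- dtiFeatureSubset(x)
  g <- groups(ft)
  age <- ages(ft)
  isTest <- ids %in% testIds
  if (sum(isTest) < 2 || sum(!isTest) < 4)
    stop("not enough participants to split train/test")
  if (a %in% config$ageCorrectAssessments) {
    x <- ageCorrect(x, age, which(!isTest & g == "control"))
  }
  mm <- fitMinMax(x[!isTest, , drop = FALSE])
  xn <- applyMinMax(mm, x)
  set.seed(.childSeed(config$seed, a))
  res <- rfeTrain(xn[!isTest, , drop = FALSE], g[!isTest],
                  cost = config$svmCost)
  testProb <- predictProb(res, xn[isTest, , drop = FALSE])
  names(testProb) <- ids[isTest]
  list(model = res, minmax = mm,
       trainLOO = res@trajectory$looAccuracy[res@selectedIteration],
       testAccuracy = probAccuracy(testProb, g[isTest]),
       testProb = testProb[testIds])
}

# natural viewing: pretrain TICA on a held-out synthetic corpus, encode,
# train the two-layer stack, predict the test participants
.runNaturalViewing <- function(cohort, testIds, config) {
  traces <- cohortTraces(cohort)
  if (length(traces) == 0) stop("cohort has no natural-viewing traces")
  part <- participants(cohort)
  ids <- names(traces)
  g <- .groupFactor(part[ids, "group"])
  isTest <- ids %in% testIds
  if (sum(isTest) < 2 || sum(!isTest) < 4)
    stop("not enough participants to split train/test")

  # pre-training corpus: separate synthetic viewers, no group effect
  set.seed(.childSeed(config$seed, "tica-pretrain"))
  ts <- config$spec@traceSpec
  corpus <- lapply(seq_len(config$pretrainParticipants), function(i) {
    generateAttentionalTraces("control", ts, groupEffect = 0,
                              durations = cohort@snippetDurations)
  })
  net <- trainTICA(corpus, config = config$tica,
                   seed = .childSeed(config$seed, "tica-init"))

  reps <- encodeCohortTraces(net, traces)
  repsTrain <- lapply(reps, function(m) m[!isTest, , drop = FALSE])
  repsTest <- lapply(reps, function(m) m[isTest, , drop = FALSE])
  res <- twoLayerClassify(repsTrain, g[!isTest], weakC = config$weakC,
                          cGrid = config$cGrid)
  testProb <- predictProb(res, repsTest)
  names(testProb) <- ids[isTest]
  list(model = res, network = net,
       trainLOO = res@looAccuracy,
       testAccuracy = probAccuracy(testProb, g[isTest]),
       testProb = testProb[testIds])
}

.writeReport <- function(report, outputDir) {
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    report[setdiff(names(report), c("subsetTable", "probabilities"))],
    file.path(outputDir, "report.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE)
  write.csv(report$subsetTable, file.path(outputDir, "subset_table.csv"),
            row.names = FALSE)
  write.csv(data.frame(id = rownames(report$probabilities),
                       report$probabilities, check.names = FALSE),
            file.path(outputDir, "test_probabilities.csv"),
            row.names = FALSE)
  invisible(outputDir)
}
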
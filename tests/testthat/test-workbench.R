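# end-to-end orchestration

fastConfig <- function(seed = 11, naturalview = TRUE) {
  spec <- cohortSpec(
    nFASD = 24, nControl = 26,
    missingness = list(prosac = c(22L, 24L), mgsac = c(20L, 22L),
                       antisac = c(21L, 23L), naturalview = c(20L, 22L),
                       dti = c(18L, 20L), psych = c(21L, 23L)),
    allComplete = c(10L, 12L),
    effectSizes = c(prosac = 1.2, antisac = 1.2, mgsac = 1.2,
                    dti = 1.2, psych = 1.2, naturalview = 2),
    traceSpec = list(nSnippets = 10L, rateHz = 40,
                     effectSnippets = 1:4),
    seed = seed)
  assessments <- c("prosac", "antisac", "mgsac", "dti", "psych")
  if (naturalview) assessments <- c(assessments, "naturalview")
  runConfig(spec = spec, assessments = assessments, cGrid = 1,
            pretrainParticipants = 4L, tica = ticaConfig(maxit = 40L),
            seed = seed)
}

test_that("the full pipeline report carries every stage's outputs", {
  cfg <- fastConfig(seed = 11)
  d <- withr::local_tempdir()
  rep <- runFullPipeline(cfg, outputDir = d)
  expect_equal(sort(rep$singleAssessment$assessment),
               sort(cfg$assessments))
  expect_true(all(rep$singleAssessment$testAccuracy >= 0 &
                    rep$singleAssessment$testAccuracy <= 1))
  expect_equal(rep$cohort$nTest, 22)
  expect_equal(nrow(rep$subsetTable), choose(6, 2))
  expect_true(all(c("accuracy", "sensitivity", "specificity") %in%
                    names(rep$fusion)))
  expect_true(all(c("ev", "evFASD", "multiYearSavings",
                    "cumulativeMiss", "per1000") %in%
                    names(rep$economics)))
  expect_match(rep$configHash, "^[0-9a-f]{32}$")
  # written artifacts
  expect_true(file.exists(file.path(d, "report.json")))
  expect_true(file.exists(file.path(d, "subset_table.csv")))
  js <- jsonlite::read_json(file.path(d, "report.json"))
  expect_equal(js$cohort$nTest, 22)
})

test_that("identical configurations reproduce the identical report", {
  cfg <- fastConfig(seed = 12, naturalview = FALSE)
  r1 <- runFullPipeline(cfg)
  r2 <- runFullPipeline(cfg)
  r1$timestamp <- r2$timestamp <- NULL
  # model objects aside, all reported numbers must match bit for bit
  expect_identical(r1$singleAssessment, r2$singleAssessment)
  expect_identical(r1$fusion, r2$fusion)
  expect_identical(r1$subsetTable, r2$subsetTable)
  expect_identical(r1$economics, r2$economics)
  expect_identical(r1$probabilities, r2$probabilities)
  expect_identical(r1$configHash, r2$configHash)
})

test_that("strong multimodal signal makes fusion at least as good as single assessments", {
  # five tabular assessments carrying independent moderate signal
  multimodalConfig <- function(seed) {
    spec <- cohortSpec(
      nFASD = 50, nControl = 50,
      missingness = list(prosac = c(46L, 46L), mgsac = c(44L, 44L),
                         antisac = c(45L, 45L),
                         naturalview = c(40L, 40L), dti = c(40L, 40L),
                         psych = c(45L, 45L)),
      allComplete = c(20L, 20L),
      effectSizes = c(prosac = 0.7, antisac = 0.7, mgsac = 0.7,
                      dti = 0.7, psych = 0.7, naturalview = 0),
      seed = seed)
    runConfig(spec = spec,
              assessments = c("prosac", "antisac", "mgsac", "dti",
                              "psych"),
              cGrid = 10, seed = seed)
  }
  wins <- vapply(1:15, function(seed) {
    rep <- runFullPipeline(multimodalConfig(500 + seed))
    rep$fusion$accuracy / 100 >=
      max(rep$singleAssessment$testAccuracy)
  }, logical(1))
  expect_gte(mean(wins), 0.7)
})

test_that("configurations round-trip through JSON and YAML files", {
  d <- withr::local_tempdir()
  cfgFile <- file.path(d, "cfg.json")
  jsonlite::write_json(list(spec = list(nFASD = 8, nControl = 9,
                                        seed = 4),
                            assessments = c("prosac", "psych"),
                            cGrid = 1, seed = 4),
                       cfgFile, auto_unbox = TRUE)
  cfg <- readRunConfig(cfgFile)
  expect_s4_class(cfg$spec, "CohortSpec")
  expect_equal(cfg$spec@nFASD, 8L)
  expect_equal(cfg$assessments, c("prosac", "psych"))
  skip_if_not_installed("yaml")
  yamlFile <- file.path(d, "cfg.yaml")
  writeLines(c("spec:", "  nFASD: 6", "  nControl: 7", "  seed: 2",
               "assessments: [prosac, psych]", "seed: 2"), yamlFile)
  cfg2 <- readRunConfig(yamlFile)
  expect_equal(cfg2$spec@nControl, 7L)
})

test_that("stage failures are tagged with the failing stage", {
  spec <- cohortSpec(
    nFASD = 24, nControl = 26,
    missingness = list(prosac = c(22L, 24L), mgsac = c(20L, 22L),
                       antisac = c(21L, 23L), naturalview = c(20L, 22L),
                       dti = c(10L, 12L), psych = c(21L, 23L)),
    allComplete = c(10L, 12L), seed = 13)
  # every DTI completer lands in the test split: its training set is empty
  cfg <- runConfig(spec = spec,
                   assessments = c("prosac", "dti"), cGrid = 1, seed = 13)
  expect_error(runFullPipeline(cfg), "stage single\\[dti\\]")
})
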
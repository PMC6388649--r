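# synthetic cohort generator

test_that("cohort matches requested sizes, demographics, and feature counts", {
  co <- generateCohort(cohortSpec(seed = 1), traces = FALSE)
  g <- groups(co)
  expect_length(g, 207)
  expect_equal(sum(g == "FASD"), 91)
  expect_equal(roundHalfUp(100 * mean(g == "FASD"), 1), 44.0)
  counts <- c(prosac = 18, antisac = 15, mgsac = 26, dti = 48, psych = 20)
  for (a in names(counts)) {
    expect_equal(ncol(featureMatrix(assessmentTable(co, a))),
                 unname(counts[a]), info = a)
  }
  expect_true(all(ages(co) >= 5 & ages(co) <= 18))
  # psychometric standardization (pooled over groups the FASD shift pulls
  # the mean down slightly; controls sit at the population calibration)
  ps <- assessmentTable(co, "psych")
  ctrl <- featureMatrix(ps)[groups(ps) == "control", ]
  expect_equal(mean(colMeans(ctrl)), 10, tolerance = 0.15)
  expect_equal(mean(apply(ctrl, 2, sd)), 3, tolerance = 0.25)
})

test_that("generation is reproducible and follows the completion plan", {
  spec <- cohortSpec(seed = 99)
  a <- generateCohort(spec, traces = FALSE)
  b <- generateCohort(spec, traces = FALSE)
  expect_identical(completionMask(a), completionMask(b))
  expect_identical(featureMatrix(assessmentTable(a, "dti")),
                   featureMatrix(assessmentTable(b, "dti")))
  expect_identical(as.data.frame(participants(a)),
                   as.data.frame(participants(b)))
  # study completion pattern
  m <- completionMask(a)
  expect_equal(unname(colSums(m)),
               c(71 + 115, 61 + 93, 67 + 106, 47 + 53, 41 + 35, 58 + 71))
  all6 <- completeAllIds(a)
  expect_length(all6, 46)
  gAll <- groups(a)[match(all6, participants(a)$id)]
  expect_equal(sum(gAll == "FASD"), 22)
  expect_equal(sum(gAll == "control"), 24)
})

test_that("inconsistent specs fail validation naming the field", {
  expect_error(cohortSpec(nInformative = c(prosac = 30L)), "nInformative")
  expect_error(cohortSpec(missingness = list(prosac = c(500L, 10L))),
               "missingness")
  expect_error(cohortSpec(nFASD = 10, nControl = 10,
                          missingness = list(prosac = c(10L, 10L),
                                             dti = c(10L, 10L)),
                          allComplete = c(11L, 10L)),
               "allComplete")
  expect_error(cohortSpec(traceSpec = list(durationRange = c(-1, 2))),
               "traceSpec")
})

test_that("zero effect sizes leave every group mean difference at noise level", {
  spec <- smallSpec(nFASD = 60, nControl = 60, effect = 0, seed = 7)
  co <- generateCohort(spec, traces = FALSE)
  for (a in c("prosac", "psych")) {
    ft <- assessmentTable(co, a)
    x <- featureMatrix(ft)
    g <- groups(ft)
    for (j in seq_len(ncol(x))) {
      d <- mean(x[g == "FASD", j]) - mean(x[g == "control", j])
      se <- sqrt(var(x[g == "FASD", j]) / sum(g == "FASD") +
                   var(x[g == "control", j]) / sum(g == "control"))
      expect_lt(abs(d), 3 * se)
    }
  }
})

test_that("empirical effect sizes converge to the specification at large n", {
  # the age trend is disabled so the standardized contrast is the only
  # systematic group difference
  spec <- cohortSpec(nFASD = 1000, nControl = 1000, effectSizes =
                       c(prosac = 0.8), ageSlope = 0,
                     missingness = NULL, seed = 3)
  co <- generateCohort(spec, traces = FALSE)
  ft <- assessmentTable(co, "prosac")
  x <- featureMatrix(ft)
  g <- groups(ft)
  inf <- head(colnames(x), 11)      # informative features lead the schema
  for (j in inf) {
    sp <- sqrt((var(x[g == "FASD", j]) + var(x[g == "control", j])) / 2)
    d <- (mean(x[g == "control", j]) - mean(x[g == "FASD", j])) / sp
    expect_lt(abs(d - 0.8), 0.1)
  }
})

test_that("DTI scalars follow the tensor formulas and stay deterministic", {
  iso <- deriveDTIScalars(1, 1, 1)
  expect_equal(iso$FA, 0)
  expect_equal(iso$MD, 1)
  expect_equal(iso$lambda_perp, 1)
  # independent evaluation of the printed formulas
  l <- c(1.7e-3, 0.3e-3, 0.3e-3)
  md <- sum(l) / 3
  fa <- sqrt(3 / 2) * sqrt(sum((l - md)^2)) / sqrt(sum(l^2))
  got <- deriveDTIScalars(l[1], l[2], l[3])
  expect_equal(got$FA, fa, tolerance = 1e-12)
  expect_equal(got$MD, md, tolerance = 1e-12)
  expect_equal(got$lambda_perp, l[2])      # lambda2 == lambda3
  expect_error(deriveDTIScalars(1, 1, 0), "positive")
  expect_error(deriveDTIScalars(1, 2, 0.5), "lambda1 >= lambda2")
  # derived columns of the generated table are functions of the
  # eigenvalue columns
  co <- generateCohort(smallSpec(seed = 5), traces = FALSE)
  x <- featureMatrix(assessmentTable(co, "dti"))
  for (roi in c("genu", "splenium")) {
    der <- deriveDTIScalars(x[, paste0(roi, "_lambda1")],
                            x[, paste0(roi, "_lambda2")],
                            x[, paste0(roi, "_lambda3")])
    expect_equal(unname(x[, paste0(roi, "_FA")]), der$FA)
    expect_equal(unname(x[, paste0(roi, "_MD")]), der$MD)
    expect_true(all(x[, paste0(roi, "_FA")] >= 0 &
                      x[, paste0(roi, "_FA")] <= 1))
  }
})

test_that("attentional traces follow the snippet count, duration, and channel contract", {
  set.seed(11)
  ts <- list(nSnippets = 70L, rateHz = 500, durationRange = c(2, 4),
             effectSnippets = 1:10,
             effectChannels = c("CIOFMJ", "topdown"))
  tr <- generateAttentionalTraces("control", ts, groupEffect = 0)
  expect_length(tr, 70)
  lens <- vapply(tr, nrow, integer(1))
  expect_true(all(lens >= 1000 & lens <= 2000))
  expect_true(all(vapply(tr, ncol, integer(1)) == 10))
  expect_equal(colnames(tr[[1]]),
               c("C", "I", "O", "F", "M", "J", "Var", "CIOFM", "CIOFMJ",
                 "topdown"))
})

test_that("null trace effect leaves channel means indistinguishable", {
  set.seed(12)
  ts <- list(nSnippets = 6L, rateHz = 50, durationRange = c(2, 4),
             effectSnippets = 1:3, effectChannels = c("topdown"))
  nPer <- 20
  chMean <- function(group) {
    vapply(seq_len(nPer), function(i) {
      tr <- generateAttentionalTraces(group, ts, groupEffect = 0)
      mean(vapply(tr, function(m) mean(m[, "topdown"]), numeric(1)))
    }, numeric(1))
  }
  a <- chMean("FASD")
  b <- chMean("control")
  se <- sqrt(var(a) / nPer + var(b) / nPer)
  expect_lt(abs(mean(a) - mean(b)), 3 * se)
})

test_that("a cohort round-trips to plain-text files", {
  co <- generateCohort(smallSpec(nFASD = 4, nControl = 4, seed = 2,
                                 nSnippets = 2L, rateHz = 25))
  d <- withr::local_tempdir()
  writeCohort(co, d)
  expect_true(file.exists(file.path(d, "prosac.csv")))
  df <- read.csv(file.path(d, "prosac.csv"), check.names = FALSE)
  expect_equal(nrow(df), 8)
  expect_equal(ncol(df), 4 + 18)
  man <- jsonlite::read_json(file.path(d, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$completeAll, 8)
  tr <- read.csv(file.path(d, "traces", paste0(man$traceParticipants[1],
                                               ".csv")),
                 check.names = FALSE)
  expect_equal(ncol(tr), 2 + 10)
  expect_equal(length(unique(tr$snippet_id)), 2)
})
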
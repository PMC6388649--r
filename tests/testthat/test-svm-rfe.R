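# SVM recursive feature elimination

test_that("a perfectly separating feature is selected with LOO accuracy 1", {
  toy <- separableToy(n = 40, nNoise = 5, seed = 1)
  xn <- applyMinMax(fitMinMax(toy$x), toy$x)
  r <- rfeTrain(xn, toy$y)
  expect_true("sep" %in% r@selectedFeatures)
  expect_equal(r@trajectory$looAccuracy[r@selectedIteration], 1.0)
  # the constructed sample is linearly separable by direct enumeration
  # on the single separating feature
  thr <- 0.5
  expect_true(all((toy$x[, "sep"] > thr) == (toy$y == "FASD")))
})

test_that("elimination evaluates d candidate sets, shrinking by one feature", {
  set.seed(2)
  d <- 18
  x <- matrix(rnorm(24 * d), 24, d, dimnames = list(NULL, paste0("f", 1:d)))
  y <- rep(c("control", "FASD"), each = 12)
  r <- rfeTrain(applyMinMax(fitMinMax(x), x), y)
  expect_equal(nrow(r@trajectory), d)
  expect_equal(r@trajectory$nActive, d:1)
  sizes <- vapply(r@featureSets, length, integer(1))
  expect_equal(sizes, d:1)
  # each active set nests in the previous one
  for (i in 2:d)
    expect_true(all(r@featureSets[[i]] %in% r@featureSets[[i - 1]]))
  # selection is the argmax, ties toward fewer features
  best <- max(which(r@trajectory$looAccuracy ==
                      max(r@trajectory$looAccuracy)))
  expect_equal(r@selectedIteration, best)
  expect_gte(r@trajectory$looAccuracy[r@selectedIteration],
             r@trajectory$looAccuracy[1])
  expect_error(rfeTrain(x, rep("FASD", 24)), "both classes")
})

test_that("normalized contribution weights sum to one in absolute value", {
  for (seed in 1:3) {
    toy <- separableToy(n = 30, nNoise = 4, seed = seed)
    r <- rfeTrain(applyMinMax(fitMinMax(toy$x), toy$x), toy$y)
    expect_equal(sum(abs(r@normalizedWeights)), 1, tolerance = 1e-10)
  }
})

test_that("probabilities are calibrated: symmetric boundary at one half, margins confident", {
  set.seed(3)
  # mirror-symmetric, balanced training set: the calibrated sigmoid is
  # antisymmetric about the decision boundary
  n <- 30
  base <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("u", "v")))
  x <- rbind(base + 1.2, -(base + 1.2))
  colnames(x) <- c("u", "v")
  y <- rep(c("FASD", "control"), each = n)
  r <- rfeTrain(x, y)
  onBoundary <- matrix(0, 1, 2, dimnames = list(NULL, c("u", "v")))
  expect_equal(unname(predictProb(r, onBoundary)), 0.5, tolerance = 1e-6)
  far <- matrix(10 * sign(r@weights), 1, length(r@weights),
                dimnames = list(NULL, names(r@weights)))
  expect_gt(predictProb(r, far), 0.9)
  p <- predictProb(r, x)
  expect_length(p, nrow(x))
  expect_true(all(p >= 0 & p <= 1))
  expect_error(predictProb(r, matrix(0, 1, 1,
                                     dimnames = list(NULL, "other"))),
               "missing")
})

test_that("the DTI classification subset keeps the 30 raw measurements", {
  co <- generateCohort(smallSpec(nFASD = 5, nControl = 5, seed = 4),
                       traces = FALSE)
  x <- featureMatrix(assessmentTable(co, "dti"))
  sub <- dtiFeatureSubset(x)
  expect_equal(ncol(x), 48)
  expect_equal(ncol(sub), 30)
  expect_false(any(grepl("FA|MD|lambda_perp", colnames(sub))))
  # region-wise order preserved and idempotent
  expect_equal(colnames(sub)[1:5],
               paste0("genu_", c("lambda1", "lambda2", "lambda3",
                                 "length_avg", "angle_avg")))
  expect_identical(dtiFeatureSubset(sub), sub)
  expect_error(dtiFeatureSubset(x[, -1]), "missing")
  # the regression subset drops only perpendicular diffusivity
  reg <- dtiRegressorSubset(x)
  expect_equal(ncol(reg), 42)
  expect_false(any(grepl("lambda_perp", colnames(reg))))
})

test_that("planted informative features are recovered across seeds", {
  hits <- vapply(1:15, function(seed) {
    set.seed(seed)
    n <- 60
    y <- rep(c("control", "FASD"), each = n / 2)
    x <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("f", 1:10)))
    x[y == "FASD", 1:3] <- x[y == "FASD", 1:3] + 1.5
    r <- rfeTrain(applyMinMax(fitMinMax(x), x), y)
    sum(paste0("f", 1:3) %in% r@selectedFeatures) >= 2
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
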
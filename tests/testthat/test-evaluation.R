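# confusion statistics, chance level, bootstrap comparison

test_that("confusion rates reproduce the screening protocol operating points", {
  # full six-assessment protocol on the 22 FASD / 24 control test group
  cr <- confusionRates(TP = 18, FN = 4, FP = 3, TN = 21)
  expect_equal(roundHalfUp(sensitivity(cr, TRUE), 1), 81.8)
  expect_equal(specificity(cr, TRUE), 87.5)
  expect_equal(accuracy(cr, TRUE), 84.78)
  # eye-movement-only screening pair
  cr2 <- confusionRates(TP = 17, FN = 5, FP = 5, TN = 19)
  expect_equal(sensitivity(cr2, TRUE), 77.27)
  expect_equal(specificity(cr2, TRUE), 79.17)
  expect_equal(accuracy(cr2, TRUE), 78.26)
  # rate identities
  expect_equal(sensitivity(cr2) + missRate(cr2), 1)
  expect_equal(specificity(cr2) + falseAlarmRate(cr2), 1)
})

test_that("confusion statistics come from labels, order-invariantly", {
  truth <- rep(c("FASD", "control"), c(6, 8))
  pred <- truth
  pred[c(1, 7)] <- c("control", "FASD")
  cr <- confusionStats(pred, truth)
  expect_equal(c(cr@TP, cr@FN, cr@FP, cr@TN), c(5, 1, 1, 7))
  perm <- sample(length(truth))
  cr2 <- confusionStats(pred[perm], truth[perm])
  expect_equal(accuracy(cr2), accuracy(cr))
  # perfect prediction
  crP <- confusionStats(truth, truth)
  expect_equal(sensitivity(crP), 1)
  expect_equal(specificity(crP), 1)
  expect_equal(missRate(crP), 0)
  expect_equal(falseAlarmRate(crP), 0)
  expect_error(confusionStats(character(0), character(0)), "empty")
  expect_error(confusionStats(truth, rep("FASD", 14)), "both classes")
})

test_that("chance level is the majority-class rate", {
  expect_equal(chanceLevel(rep(c("FASD", "control"), c(22, 24))), 52.17)
  expect_equal(chanceLevel(rep(c("FASD", "control"), each = 10)), 50)
  expect_equal(chanceLevel(rep("FASD", 5)), 100)
  expect_error(chanceLevel(character(0)), "empty")
})

test_that("relative improvement follows the reporting convention", {
  expect_equal(roundHalfUp(relativeImprovement(78.26, 69.57), 1), 12.5)
  expect_equal(roundHalfUp(relativeImprovement(78.26, 71.74), 1), 9.1)
  expect_equal(relativeImprovement(50, 50), 0)
})

# simple trainers over a one-dimensional signal for bootstrap tests
.thresholdTrainer <- function(column) {
  function(x, y, xtest) {
    thr <- mean(tapply(x[, column], y, mean))
    up <- mean(x[y == "FASD", column]) > mean(x[y == "control", column])
    pred <- (xtest[, column] > thr) == up
    ifelse(pred, "FASD", "control")
  }
}

test_that("stratified bootstrap keeps class counts and rep structure", {
  set.seed(1)
  n <- 40
  y <- rep(c("control", "FASD"), c(24, 16))
  x <- cbind(sig = rnorm(n) + (y == "FASD"), noise = rnorm(n))
  xte <- cbind(sig = rnorm(20) + rep(0:1, each = 10), noise = rnorm(20))
  yte <- rep(c("control", "FASD"), each = 10)
  seen <- list()
  counter <- function(x, y, xtest) {
    seen[[length(seen) + 1]] <<- table(y)
    rep("control", nrow(xtest))
  }
  out <- bootstrapCompare(list(cnt = counter), x, y, xte, yte, reps = 20,
                          seed = 5)
  expect_equal(nrow(out$accuracies), 20)
  expect_length(seen, 20)
  for (tb in seen) {
    expect_equal(unname(tb["control"]), 24)
    expect_equal(unname(tb["FASD"]), 16)
  }
})

test_that("identical deterministic trainers tie with ANOVA p = 1", {
  set.seed(2)
  n <- 30
  y <- rep(c("control", "FASD"), each = 15)
  x <- cbind(sig = rnorm(n) + 2 * (y == "FASD"))
  xte <- cbind(sig = rnorm(16) + 2 * rep(0:1, each = 8))
  yte <- rep(c("control", "FASD"), each = 8)
  tr <- .thresholdTrainer("sig")
  out <- bootstrapCompare(list(a = tr, b = tr), x, y, xte, yte,
                          reps = 10, seed = 3)
  expect_equal(out$accuracies[, "a"], out$accuracies[, "b"])
  expect_equal(out$anovaP, 1)
  expect_false(any(out$tukey$significant))
})

test_that("a large accuracy gap is flagged by Tukey in most meta-repetitions", {
  flagged <- vapply(1:10, function(meta) {
    set.seed(200 + meta)
    n <- 40
    y <- rep(c("control", "FASD"), each = 20)
    x <- cbind(sig = rnorm(n) + 1.6 * (y == "FASD"), noise = rnorm(n))
    xte <- cbind(sig = rnorm(30) + 1.6 * rep(0:1, c(15, 15)),
                 noise = rnorm(30))
    yte <- rep(c("control", "FASD"), c(15, 15))
    out <- bootstrapCompare(list(good = .thresholdTrainer("sig"),
                                 bad = .thresholdTrainer("noise")),
                            x, y, xte, yte, reps = 20, seed = meta)
    any(out$tukey$significant)
  }, logical(1))
  expect_gte(mean(flagged), 0.9)
})

test_that("trainer failures are recorded without aborting the comparison", {
  set.seed(4)
  y <- rep(c("control", "FASD"), each = 10)
  x <- cbind(sig = rnorm(20))
  failing <- function(x, y, xtest) stop("bad resample")
  out <- bootstrapCompare(list(ok = .thresholdTrainer("sig"),
                               bad = failing),
                          x, y, x, y, reps = 3, seed = 1)
  expect_equal(length(out$failures), 3)
  expect_true(all(is.na(out$accuracies[, "bad"])))
  expect_true(all(!is.na(out$accuracies[, "ok"])))
})
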
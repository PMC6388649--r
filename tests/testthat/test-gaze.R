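# natural-viewing pipeline: trace extraction, filtering, two-layer stack

test_that("trace extraction looks up z-scored map values at the gaze", {
  m <- outer(dnorm(1:21, 11, 3), dnorm(1:21, 11, 3))
  z <- (m - mean(m)) / sd(as.vector(m))
  tr <- extractAttentionalTrace(list(C = m),
                                data.frame(frame = 1, x = 11, y = 11))
  expect_equal(unname(tr[1, "C"]), max(z))
  # constant map z-scores to zero
  tr0 <- extractAttentionalTrace(list(C = matrix(5, 4, 4)),
                                 data.frame(frame = 1, x = 2, y = 3))
  expect_equal(unname(tr0[1, "C"]), 0)
  # one output dimension per supplied channel
  maps <- stats::setNames(replicate(10, matrix(rnorm(16), 4, 4),
                                    simplify = FALSE),
                          c("C", "I", "O", "F", "M", "J", "Var",
                            "CIOFM", "CIOFMJ", "topdown"))
  tr10 <- extractAttentionalTrace(maps, data.frame(frame = c(1, 1),
                                                   x = c(2, 3),
                                                   y = c(2, 1)))
  expect_equal(dim(tr10), c(2, 10))
  # out-of-screen samples are marked missing
  trNA <- extractAttentionalTrace(list(C = matrix(rnorm(16), 4, 4)),
                                  data.frame(frame = 1, x = 9, y = 1))
  expect_true(is.na(trNA[1, "C"]))
  expect_error(extractAttentionalTrace(list(C = matrix(0, 0, 0)),
                                       data.frame(frame = 1, x = 1, y = 1)),
               "empty")
})

test_that("the t-test filter applies the Bonferroni threshold per dimension", {
  set.seed(1)
  n <- 60
  y <- rep(c("control", "FASD"), each = n / 2)
  x <- matrix(rnorm(n * 100), n, 100)
  flt <- tTestFilter(x, y, alpha = 0.05)
  expect_equal(flt$threshold, 5e-4)       # 0.05 / 100
  # p-values agree with the standard Welch two-sample t-test
  for (j in 1:3) {
    pv <- t.test(x[y == "FASD", j], x[y == "control", j])$p.value
    expect_equal(flt$pvalue[j], pv, tolerance = 1e-12)
  }
  # a constant dimension carries no information and is dropped
  x2 <- cbind(x[, 1:3], rep(1, n))
  expect_warning(flt2 <- tTestFilter(x2, y), "zero-variance")
  expect_false(flt2$keep[4])
  expect_error(tTestFilter(x, rep("FASD", n)), "both classes")
})

test_that("a strongly separated dimension survives filtering across seeds", {
  kept <- vapply(1:20, function(seed) {
    set.seed(seed)
    n <- 60
    y <- rep(c("control", "FASD"), each = n / 2)
    x <- matrix(rnorm(n * 50), n, 50)
    x[y == "FASD", 1] <- x[y == "FASD", 1] + 2
    tTestFilter(x, y, alpha = 0.05)$keep[1]
  }, logical(1))
  expect_gte(mean(kept), 0.95)
})

test_that("perfectly informative snippets drive the stack to LOO accuracy 1", {
  set.seed(2)
  n <- 24
  y <- rep(c("control", "FASD"), each = n / 2)
  lab <- as.numeric(y == "FASD")
  reps <- replicate(6, cbind(lab + rnorm(n, 0, 0.01)), simplify = FALSE)
  res <- twoLayerClassify(reps, y, cGrid = c(1, 10))
  expect_equal(res@looAccuracy, 1.0)
  expect_true(all(res@finalProb[y == "FASD"] > 0.5))
  # selected snippets are exactly the non-zero second-layer coefficients
  expect_identical(res@selectedSnippets,
                   which(res@secondLayer@weights != 0))
  expect_equal(ncol(res@snippetProbs), 6)
  expect_error(twoLayerClassify(reps, rep("FASD", n)), "2 participants")
})

test_that("signal snippets separate groups through the full stack", {
  sig <- signalReps(n = 30, nSnippets = 12, signalSnippets = 4,
                    shift = 2, seed = 3)
  res <- twoLayerClassify(sig$reps, sig$y, cGrid = c(0.1, 1, 10))
  expect_gt(res@looAccuracy, 0.8)
  p <- predictProb(res, sig$reps)
  expect_gt(probAccuracy(p, sig$y), 0.9)
  # missing snippets are imputed and still predict
  repsNA <- sig$reps
  repsNA[[1]][2, ] <- NA
  p2 <- predictProb(res, repsNA)
  expect_length(p2, 30)
  expect_true(all(p2 >= 0 & p2 <= 1))
})

test_that("a zero-effect stack stays at chance over many seeds", {
  accs <- vapply(1:50, function(seed) {
    set.seed(seed)
    nTr <- 20; nTe <- 10
    y <- rep(c("control", "FASD"), each = (nTr + nTe) / 2)
    idx <- c(1:(nTr / 2), (nTr + nTe) / 2 + 1:(nTr / 2))
    reps <- replicate(8, matrix(rnorm((nTr + nTe) * 4), nTr + nTe, 4),
                      simplify = FALSE)
    repsTr <- lapply(reps, function(m) m[idx, , drop = FALSE])
    repsTe <- lapply(reps, function(m) m[-idx, , drop = FALSE])
    res <- twoLayerClassify(repsTr, y[idx], cGrid = c(0.1, 1))
    probAccuracy(predictProb(res, repsTe), y[-idx])
  }, numeric(1))
  nTotal <- 50 * 10
  band <- qbinom(c(0.025, 0.975), nTotal, 0.5) / nTotal
  expect_gte(mean(accs), band[1])
  expect_lte(mean(accs), band[2])
})

test_that("large trace effects in a snippet subset yield high held-out accuracy", {
  # end-to-end at the study's snippet count: effect in 10 of 70 snippets
  set.seed(4)
  ts <- list(nSnippets = 70L, rateHz = 50, durationRange = c(2, 4),
             effectSnippets = 1:10,
             effectChannels = c("F", "J", "CIOFMJ", "topdown"))
  durations <- runif(70, 2, 4)
  n <- 100
  y <- rep(c("control", "FASD"), each = n / 2)
  traces <- lapply(seq_len(n), function(i) {
    generateAttentionalTraces(y[i], ts, groupEffect = 3,
                              durations = durations)
  })
  names(traces) <- sprintf("P%03d", seq_len(n))
  corpus <- lapply(1:4, function(i)
    generateAttentionalTraces("control", ts, groupEffect = 0,
                              durations = durations))
  net <- trainTICA(corpus, config = ticaConfig(maxit = 60L), seed = 1)
  reps <- encodeCohortTraces(net, traces)
  isTest <- seq_len(n) %in% c(36:50, 86:100)
  repsTr <- lapply(reps, function(m) m[!isTest, , drop = FALSE])
  repsTe <- lapply(reps, function(m) m[isTest, , drop = FALSE])
  res <- twoLayerClassify(repsTr, y[!isTest], cGrid = c(0.1, 1, 10))
  acc <- probAccuracy(predictProb(res, repsTe), y[isTest])
  expect_gte(acc, 0.85)
  # discriminative snippets concentrate where the effect was injected
  expect_gt(mean(res@selectedSnippets %in% 1:10), 0.2)
})
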
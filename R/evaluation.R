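# confusion statistics, chance level, bootstrap classifier comparison

#' Confusion statistics with FASD as the positive class
#'
#' @param predicted predicted labels (`control` / `FASD`).
#' @param truth true labels; both classes must be represented.
#' @return a [ConfusionRates].
#' @examples
#' cr <- confusionRates(TP = 18, FN = 4, FP = 3, TN = 21)
#' sensitivity(cr, percent = TRUE)   # 81.82
#' accuracy(cr, percent = TRUE)      # 84.78
#' @export
confusionStats <- function(predicted, truth) {
  if (length(truth) == 0) stop("empty label vectors")
  p <- .groupFactor(predicted)
  t <- .groupFactor(truth)
  stopifnot(length(p) == length(t))
  if (nlevels(droplevels(t)) < 2)
    stop("both classes must be represented in the truth")
  confusionRates(TP = sum(p == "FASD" & t == "FASD"),
                 FN = sum(p == "control" & t == "FASD"),
                 FP = sum(p == "FASD" & t == "control"),
                 TN = sum(p == "control" & t == "control"))
}

#' @describeIn confusionStats build directly from counts.
#' @param TP,FN,FP,TN confusion counts.
#' @export
confusionRates <- function(TP, FN, FP, TN) {
  new("ConfusionRates", TP = as.integer(TP), FN = as.integer(FN),
      FP = as.integer(FP), TN = as.integer(TN))
}

.rate <- function(num, den, percent) {
  r <- num / den
  if (percent) roundHalfUp(100 * r, 2) else r
}

#' Sensitivity (detection rate) of a confusion matrix
#' @param x a [ConfusionRates].
#' @param percent report as a percentage rounded to 2 decimals.
#' @return rate.
#' @export
sensitivity <- function(x, percent = FALSE)
  .rate(x@TP, x@TP + x@FN, percent)

#' Specificity (true negative rate)
#' @inheritParams sensitivity
#' @export
specificity <- function(x, percent = FALSE)
  .rate(x@TN, x@TN + x@FP, percent)

#' Miss rate (1 - sensitivity)
#' @inheritParams sensitivity
#' @export
missRate <- function(x, percent = FALSE)
  .rate(x@FN, x@TP + x@FN, percent)

#' False alarm rate (1 - specificity)
#' @inheritParams sensitivity
#' @export
falseAlarmRate <- function(x, percent = FALSE)
  .rate(x@FP, x@TN + x@FP, percent)

#' Accuracy of a confusion matrix
#' @inheritParams sensitivity
#' @export
accuracy <- function(x, percent = FALSE)
  .rate(x@TP + x@TN, x@TP + x@FN + x@FP + x@TN, percent)

setMethod("show", "ConfusionRates", function(object) {
  cat(sprintf("ConfusionRates (FASD positive): TP %d  FN %d  FP %d  TN %d\n",
              object@TP, object@FN, object@FP, object@TN))
  cat(sprintf("  sensitivity %.2f%%  specificity %.2f%%  accuracy %.2f%%\n",
              sensitivity(object, TRUE), specificity(object, TRUE),
              accuracy(object, TRUE)))
})

#' Chance level: majority-class rate
#'
#' Accuracy of the prior-only classifier that always predicts the
#' majority class of the evaluation set.
#'
#' @param truth label vector.
#' @param percent report as a percentage rounded to 2 decimals
#'   (default `TRUE`).
#' @return majority-class fraction.
#' @examples
#' chanceLevel(rep(c("FASD", "control"), c(22, 24)))   # 52.17
#' @export
chanceLevel <- function(truth, percent = TRUE) {
  if (length(truth) == 0) stop("empty label vector")
  r <- max(table(.groupFactor(truth))) / length(truth)
  if (percent) roundHalfUp(100 * r, 2) else r
}

#' Relative improvement of one accuracy over another
#'
#' `100 * (new - base) / base`, the convention used when comparing a
#' fused accuracy against the accuracies of its constituent
#' assessments.
#'
#' @param new,base accuracies (any common scale).
#' @return percentage improvement.
#' @examples
#' relativeImprovement(78.26, 69.57)   # ~ 12.5
#' @export
relativeImprovement <- function(new, base) {
  100 * (new - base) / base
}

#' Stratified-bootstrap comparison of classifiers
#'
#' Repeats, `reps` times: resample the training set with replacement
#' within each group (keeping the per-group sample counts), train every
#' classifier on the resample, and measure its accuracy on the fixed
#' test set.  The per-classifier accuracy samples are compared with a
#' one-way ANOVA and pairwise Tukey honest-significant-difference tests
#' at the given level.
#'
#' @param trainers named list of functions `f(x, y, xtest)` returning
#'   predicted labels for `xtest`.
#' @param x,y training features and labels.
#' @param xtest,ytest fixed test set.
#' @param reps bootstrap repetitions (default 20).
#' @param seed RNG seed.
#' @param alpha significance level for the Tukey flags (default 0.05).
#' @return list: `accuracies` (reps x classifiers matrix; failed reps
#'   `NA`), `mean`, `se`, `anovaP`, `tukey` (data.frame pair / diff /
#'   pAdj / significant), `failures`.
#' @export
bootstrapCompare <- function(trainers, x, y, xtest, ytest, reps = 20,
                             seed = 1L, alpha = 0.05) {
  stopifnot(reps >= 2, is.list(trainers), length(trainers) >= 1)
  x <- .featureMatrix(x)
  xtest <- .featureMatrix(xtest)
  f <- .groupFactor(y)
  ftest <- .groupFactor(ytest)
  if (nlevels(droplevels(f)) < 2 || nlevels(droplevels(ftest)) < 2)
    stop("both classes must be present in train and test")
  nm <- names(trainers) %||% sprintf("clf%d", seq_along(trainers))
  set.seed(as.integer(seed))
  acc <- matrix(NA_real_, reps, length(trainers),
                dimnames = list(NULL, nm))
  failures <- list()
  for (r in seq_len(reps)) {
    idx <- unlist(lapply(levels(f), function(g) {
      ig <- which(f == g)
      sample(ig, length(ig), replace = TRUE)
    }))
    for (k in seq_along(trainers)) {
      pred <- tryCatch(trainers[[k]](x[idx, , drop = FALSE], f[idx], xtest),
                       error = function(e) e)
      if (inherits(pred, "error")) {
        failures[[length(failures) + 1]] <-
          list(rep = r, classifier = nm[k], message = conditionMessage(pred))
      } else {
        acc[r, k] <- mean(.groupFactor(pred) == ftest)
      }
    }
  }
  mu <- colMeans(acc, na.rm = TRUE)
  se <- apply(acc, 2, function(a) sd(a, na.rm = TRUE) /
                sqrt(sum(!is.na(a))))
  long <- data.frame(accuracy = as.vector(acc),
                     classifier = factor(rep(nm, each = reps)))
  long <- long[!is.na(long$accuracy), ]
  long$classifier <- droplevels(long$classifier)
  if (nlevels(long$classifier) > 1 && var(long$accuracy) > 0) {
    fit <- aov(accuracy ~ classifier, data = long)
    anovaP <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- TukeyHSD(fit, conf.level = 1 - alpha)$classifier
    tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                        pAdj = tk[, "p adj"],
                        significant = tk[, "p adj"] < alpha,
                        row.names = NULL)
  } else {
    # all accuracies tied (or a single classifier): no evidence of a
    # difference
    anovaP <- 1
    tukey <- data.frame(pair = character(0), diff = numeric(0),
                        pAdj = numeric(0), significant = logical(0))
  }
  list(accuracies = acc, mean = mu, se = se, anovaP = anovaP,
       tukey = tukey, failures = failures)
}
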
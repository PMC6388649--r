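# probability-level fusion across assessments

#' Iterative train-test fusion of per-assessment probabilities
#'
#' For the participants with complete data, fuses the per-assessment
#' probabilities of FASD: in each iteration one participant is held out,
#' an L1-logistic classifier (C chosen by inner leave-one-out over
#' `cGrid`) is trained on the remaining participants' probability
#' vectors, and the held-out participant is predicted.  The iteration
#' ends when every participant has been the test sample once; aggregate
#' confusion statistics are computed from the held-out predictions at
#' the 0.5 threshold.
#'
#' @param probTable participants x assessments numeric matrix (or
#'   data.frame) of probabilities of FASD.
#' @param labels true group labels.
#' @param subset assessments (column names) to fuse; default all.
#' @param cGrid C grid for the inner leave-one-out selection; a single
#'   value skips the inner loop.
#' @return a [FusionResult].
#' @export
iterativeTrainTest <- function(probTable, labels,
                               subset = colnames(probTable),
                               cGrid = c(0.01, 0.1, 1, 10, 100)) {
  if (length(subset) == 0) stop("assessment subset must be non-empty")
  x <- .featureMatrix(probTable)
  missing <- setdiff(subset, colnames(x))
  if (length(missing))
    stop("assessment(s) not in probability table: ",
         paste(missing, collapse = ", "))
  x <- x[, subset, drop = FALSE]
  f <- .groupFactor(labels)
  n <- nrow(x)
  stopifnot(length(f) == n)
  prob <- numeric(n)
  for (i in seq_len(n)) {
    ytr <- f[-i]
    if (nlevels(droplevels(ytr)) < 2)
      stop("a class is absent from a training fold")
    xtr <- x[-i, , drop = FALSE]
    C <- if (length(cGrid) == 1) cGrid else chooseL1C(xtr, ytr, cGrid)$C
    m <- fitL1LogReg(xtr, ytr, C = C)
    prob[i] <- predictProb(m, x[i, , drop = FALSE])
  }
  label <- ifelse(prob > 0.5, "FASD", "control")
  ids <- rownames(x) %||% sprintf("P%03d", seq_len(n))
  new("FusionResult",
      predictions = data.frame(id = ids, truth = as.character(f),
                               probability = prob, label = label,
                               stringsAsFactors = FALSE),
      subset = subset,
      rates = confusionStats(label, f))
}

#' Accuracy of a fusion result
#'
#' @param x a [FusionResult].
#' @return held-out accuracy fraction.
#' @export
fusionAccuracy <- function(x) {
  stopifnot(is(x, "FusionResult"))
  accuracy(x@rates)
}

#' Evaluate assessment subsets by fused held-out accuracy
#'
#' Runs [iterativeTrainTest()] for every subset and ranks subsets by
#' accuracy (ties keep the input order).
#'
#' @param probTable,labels,cGrid as in [iterativeTrainTest()].
#' @param subsets list of character vectors of assessment names; the
#'   helper [assessmentPairs()] builds all pairs.
#' @return data.frame: subset (comma-joined), size, accuracy,
#'   sensitivity, specificity, sorted by decreasing accuracy.
#' @export
evaluateSubsets <- function(probTable, labels, subsets,
                            cGrid = c(0.01, 0.1, 1, 10, 100)) {
  stopifnot(is.list(subsets), length(subsets) > 0)
  rows <- lapply(subsets, function(s) {
    r <- iterativeTrainTest(probTable, labels, subset = s, cGrid = cGrid)
    data.frame(subset = paste(s, collapse = ","),
               size = length(s),
               accuracy = accuracy(r@rates),
               sensitivity = sensitivity(r@rates),
               specificity = specificity(r@rates))
  })
  out <- do.call(rbind, rows)
  out[order(-out$accuracy), , drop = FALSE]
}

#' All pairs of assessment names
#'
#' @param assessments character vector.
#' @return list of length-2 character vectors (`choose(k, 2)` of them).
#' @export
assessmentPairs <- function(assessments) {
  cmb <- utils::combn(assessments, 2, simplify = FALSE)
  cmb
}

setMethod("show", "FusionResult", function(object) {
  cat(sprintf("FusionResult [%s]: accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%\n",
              paste(object@subset, collapse = "+"),
              100 * accuracy(object@rates),
              100 * sensitivity(object@rates),
              100 * specificity(object@rates)))
})
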
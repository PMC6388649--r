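# cross-assessment multilinear regression

#' Fit an ordinary least-squares multilinear model
#'
#' Fits `E(Y|X) = b0 + sum_i b_i x_i` by minimizing the sum of squared
#' residuals, and reports the squared correlation of response and fit
#' together with the overall F-test of the regression.  Rank-deficient
#' designs get the minimum-norm solution with a warning.
#'
#' @param y numeric response.
#' @param x regressor matrix (observations x regressors).
#' @return a [MultilinearModel].
#' @examples
#' x <- cbind(a = 1:10)
#' m <- fitMultilinear(2 + 3 * x[, 1], x)
#' c(m@intercept, m@coefficients, m@r2)
#' @export
fitMultilinear <- function(y, x) {
  x <- .featureMatrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  p <- ncol(x)
  stopifnot(length(y) == n)
  if (n <= p + 1) stop("need more observations than regressors plus one")
  X <- cbind(`(Intercept)` = 1, x)
  qrX <- qr(X)
  rank <- qrX$rank
  if (rank < ncol(X)) {
    warning("rank-deficient design; returning the minimum-norm solution")
    s <- svd(X)
    pos <- s$d > max(s$d) * 1e-10
    beta <- s$v[, pos, drop = FALSE] %*%
      ((t(s$u[, pos, drop = FALSE]) %*% y) / s$d[pos])
    beta <- drop(beta)
  } else {
    beta <- qr.coef(qrX, y)
  }
  fitted <- drop(X %*% beta)
  ssr <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 0 else max(0, min(1, 1 - ssr / sst))
  df1 <- rank - 1
  df2 <- n - rank
  fstat <- if (df1 > 0 && df2 > 0 && r2 < 1) {
    (r2 / df1) / ((1 - r2) / df2)
  } else if (r2 >= 1) Inf else NA_real_
  pvalue <- if (is.na(fstat)) NA_real_ else pf(fstat, df1, df2,
                                              lower.tail = FALSE)
  new("MultilinearModel",
      intercept = unname(beta[1]),
      coefficients = stats::setNames(beta[-1], colnames(x)),
      fitted = fitted, r2 = r2, fstat = fstat,
      df1 = as.numeric(df1), df2 = as.numeric(df2),
      pvalue = pvalue, rank = as.integer(rank))
}

#' Percentage of one assessment's features predictable from another
#'
#' For every ordered pair of assessments (A, B), regresses each of B's
#' features on all of A's features and reports the percentage of B's
#' features whose overall regression F-test is significant.  Run on
#' complete-data participants.
#'
#' @param featureList named list of feature matrices, all with the same
#'   rows (participants).  For DTI pass [dtiRegressorSubset()]; for
#'   natural viewing pass the selected snippet probabilities.
#' @param alpha significance level (default 0.05, uncorrected).
#' @return square percentage matrix; entry `[A, B]` = % of B's features
#'   significantly predicted by A's features; diagonal `NA`.
#' @export
significantRatioMatrix <- function(featureList, alpha = 0.05) {
  stopifnot(is.list(featureList), !is.null(names(featureList)))
  nm <- names(featureList)
  featureList <- lapply(featureList, .featureMatrix)
  n <- unique(vapply(featureList, nrow, integer(1)))
  if (length(n) != 1)
    stop("all assessments must cover the same participants")
  out <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
  for (a in nm) {
    for (b in setdiff(nm, a)) {
      X <- featureList[[a]]
      sig <- vapply(seq_len(ncol(featureList[[b]])), function(j) {
        m <- suppressWarnings(fitMultilinear(featureList[[b]][, j], X))
        !is.na(m@pvalue) && m@pvalue < alpha
      }, logical(1))
      out[a, b] <- 100 * mean(sig)
    }
  }
  out
}

#' Predict one assessment's outcome probability from another's features
#'
#' Regresses the held-out differentiation probability of assessment B on
#' the features of assessment A and reports the squared correlation and
#' the overall F-test.
#'
#' @param featuresA regressor matrix.
#' @param outcomeB probability vector in \[0, 1\].
#' @param alpha significance level.
#' @return list: `r2`, `pvalue`, `significant`.
#' @export
outcomePredictionR2 <- function(featuresA, outcomeB, alpha = 0.05) {
  if (any(outcomeB < 0 | outcomeB > 1))
    stop("outcome probabilities must lie in [0, 1]")
  m <- fitMultilinear(outcomeB, featuresA)
  list(r2 = m@r2, pvalue = m@pvalue,
       significant = !is.na(m@pvalue) && m@pvalue < alpha)
}

#' Outcome-probability r2 matrix across assessments
#'
#' Entry `[A, B]` is the squared correlation attained when predicting
#' assessment B's held-out differentiation probability from assessment
#' A's features; non-significant predictions (overall F-test at
#' `alpha`) are reported as `NA`.
#'
#' @param featureList named list of regressor matrices (same rows).
#' @param outcomeList named list of probability vectors in \[0, 1\],
#'   same names and rows.
#' @param alpha significance level.
#' @return list: `r2` matrix (diagonal `NA`), `pvalue` matrix.
#' @export
outcomeR2Matrix <- function(featureList, outcomeList, alpha = 0.05) {
  stopifnot(identical(sort(names(featureList)), sort(names(outcomeList))))
  nm <- names(featureList)
  r2 <- pv <- matrix(NA_real_, length(nm), length(nm),
                     dimnames = list(nm, nm))
  for (a in nm) {
    for (b in setdiff(nm, a)) {
      res <- outcomePredictionR2(featureList[[a]], outcomeList[[b]],
                                 alpha = alpha)
      pv[a, b] <- res$pvalue
      r2[a, b] <- if (isTRUE(res$significant)) res$r2 else NA_real_
    }
  }
  list(r2 = r2, pvalue = pv)
}

#' Cross-assessment regression report
#'
#' Computes the feature-level significant-ratio matrix and the
#' outcome-probability r2 matrix and, optionally, writes them as CSV
#' plus a JSON summary.
#'
#' @param featureList named list of regressor matrices over the same
#'   (complete-data) participants.
#' @param outcomeList named list of held-out probability vectors; may
#'   be `NULL` to skip the outcome panel.
#' @param alpha significance level.
#' @param dir optional output directory.
#' @return list with `featureRatio`, and (when outcomes are given)
#'   `outcomeR2` and `outcomePvalue`.
#' @export
crossPredictionReport <- function(featureList, outcomeList = NULL,
                                  alpha = 0.05, dir = NULL) {
  out <- list(featureRatio = significantRatioMatrix(featureList, alpha))
  if (!is.null(outcomeList)) {
    om <- outcomeR2Matrix(featureList, outcomeList, alpha)
    out$outcomeR2 <- om$r2
    out$outcomePvalue <- om$pvalue
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(out$featureRatio, file.path(dir, "feature_ratio.csv"))
    if (!is.null(out$outcomeR2))
      write.csv(out$outcomeR2, file.path(dir, "outcome_r2.csv"))
    jsonlite::write_json(lapply(out, function(m)
      as.data.frame(m, check.names = FALSE)),
      file.path(dir, "cross_prediction.json"),
      auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  out
}

setMethod("show", "MultilinearModel", function(object) {
  cat(sprintf("MultilinearModel: %d regressors (rank %d), r2 = %.4f, F(%g, %g) = %.3f, p = %.3g\n",
              length(object@coefficients), object@rank, object@r2,
              object@df1, object@df2, object@fstat, object@pvalue))
})
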
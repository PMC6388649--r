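# SVM recursive feature elimination with leave-one-out selection

# linear soft-margin SVM with FASD-positive orientation.
# Returns weights w, bias b with decision value f(x) = x %*% w + b,
# f > 0 => FASD, plus the support vector index set (needed for the exact
# LOO shortcut: removing a non-support vector leaves the solution
# unchanged, so such points are always classified correctly in LOO).
.linearSVM <- function(x, y, cost) {
  f <- .groupFactor(y)
  m <- e1071::svm(x, f, kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(t(m$coefs) %*% m$SV)
  b <- -m$rho
  # e1071 orients the decision value toward the first class present in
  # the data ordering; flip to FASD-positive if needed
  first <- as.character(f[1])
  if (first == "control") {
    w <- -w
    b <- -b
  }
  list(w = w, b = b, sv = m$index)
}

.svmPredictFASD <- function(fit, x) {
  drop(x %*% fit$w + fit$b) > 0
}

# exact leave-one-out accuracy of the linear SVM on (x, y)
.looAccuracy <- function(x, y, cost) {
  n <- nrow(x)
  full <- .linearSVM(x, y, cost)
  isFASD <- .groupFactor(y) == "FASD"
  correct <- .svmPredictFASD(full, x) == isFASD
  for (i in full$sv) {
    fit <- .linearSVM(x[-i, , drop = FALSE], y[-i], cost)
    correct[i] <- .svmPredictFASD(fit, x[i, , drop = FALSE]) == isFASD[i]
  }
  mean(correct)
}

# Platt sigmoid calibration: P(FASD | f) = 1 / (1 + exp(A f + B)), fit by
# maximum likelihood on the training decision values with the usual
# smoothed targets
.plattFit <- function(f, isFASD) {
  np <- sum(isFASD)
  nn <- sum(!isFASD)
  t <- ifelse(isFASD, (np + 1) / (np + 2), 1 / (nn + 2))
  nll <- function(par) {
    z <- par[1] * f + par[2]
    sum(t * .log1pexpNeg(-z) + (1 - t) * .log1pexpNeg(z))
  }
  opt <- optim(c(-1, 0), nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  opt$par
}

.plattProb <- function(platt, f) {
  .sigmoid(-(platt[1] * f + platt[2]))
}

#' @describeIn rfeTrain workhorse on a normalized numeric matrix.
#'
#' @param y group labels (`control` / `FASD`), required for the matrix
#'   method.
#' @param cost soft-margin cost of the linear SVM (default 1).
#'
#' @details
#' At each iteration a linear soft-margin SVM is trained on the active
#' features, its exact leave-one-out accuracy is recorded, and the
#' feature with the smallest contribution (squared weight, ties broken
#' toward the lowest column index) is eliminated, until one feature
#' remains: `d` candidate feature sets for `d` input features.  The
#' iteration with the best LOO accuracy is selected, ties resolved
#' toward fewer features.  The selected classifier is refit and a
#' Platt-style sigmoid is calibrated on its training decision values so
#' that held-out participants receive a probability of FASD.  The
#' selected model's contribution weights are also reported normalized so
#' their absolute values sum to 1.
#' @export
setMethod("rfeTrain", "matrix", function(x, y, cost = 1) {
  x <- .featureMatrix(x)
  f <- .groupFactor(y)
  if (nlevels(droplevels(f)) < 2)
    stop("training data must contain both classes")
  if (min(table(f)) < 2) stop("need at least 2 participants per class")
  d <- ncol(x)
  active <- seq_len(d)
  featureSets <- weightSets <- vector("list", d)
  looAcc <- numeric(d)
  for (it in seq_len(d)) {
    xa <- x[, active, drop = FALSE]
    fit <- .linearSVM(xa, f, cost)
    looAcc[it] <- .looAccuracy(xa, f, cost)
    featureSets[[it]] <- colnames(x)[active]
    weightSets[[it]] <- stats::setNames(fit$w, colnames(x)[active])
    if (length(active) > 1) {
      drop1 <- which.min(fit$w^2)       # ties: lowest column index
      active <- active[-drop1]
    }
  }
  # best accuracy; ties toward fewer features (later iteration)
  best <- max(which(looAcc == max(looAcc)))
  selFeatures <- featureSets[[best]]
  xa <- x[, selFeatures, drop = FALSE]
  fit <- .linearSVM(xa, f, cost)
  dv <- drop(xa %*% fit$w + fit$b)
  platt <- .plattFit(dv, f == "FASD")
  w <- stats::setNames(fit$w, selFeatures)
  new("RFEResult",
      trajectory = data.frame(iteration = seq_len(d),
                              nActive = d - seq_len(d) + 1L,
                              looAccuracy = looAcc),
      featureSets = featureSets, weightSets = weightSets,
      selectedIteration = as.integer(best),
      selectedFeatures = selFeatures,
      normalizedWeights = w / sum(abs(w)),
      weights = w, bias = fit$b, platt = platt, cost = cost)
})

#' @describeIn rfeTrain labels and features taken from the table.
#' @export
setMethod("rfeTrain", "FeatureTable", function(x, cost = 1) {
  rfeTrain(featureMatrix(x), groups(x), cost = cost)
})

#' @describeIn predictProb probability of FASD from the calibrated
#'   selected SVM; `x` must already be normalized with the training
#'   [MinMaxModel] and contain the selected features.
#' @export
setMethod("predictProb", "RFEResult", function(object, x) {
  x <- .featureMatrix(x)
  missing <- setdiff(object@selectedFeatures, colnames(x))
  if (length(missing))
    stop("selected feature(s) missing from data: ",
         paste(missing, collapse = ", "))
  xa <- x[, object@selectedFeatures, drop = FALSE]
  dv <- drop(xa %*% object@weights + object@bias)
  .plattProb(object@platt, dv)
})

#' Classification accuracy of probability predictions
#'
#' Labels a participant FASD when the probability exceeds 0.5 and
#' compares against the true groups.
#'
#' @param prob probabilities of FASD.
#' @param truth true group labels.
#' @return fraction correct.
#' @export
probAccuracy <- function(prob, truth) {
  mean((prob > 0.5) == (.groupFactor(truth) == "FASD"))
}

#' Restrict a DTI feature table to the raw measurements
#'
#' The 48-column DTI table holds, for each of the six corpus callosum
#' regions (genu, rostral body, anterior midbody, posterior midbody,
#' isthmus, splenium), the three tensor eigenvalues, mean fiber length,
#' mean angle, and the derived scalars FA, MD, and perpendicular
#' diffusivity.  The derived scalars are deterministic functions of the
#' eigenvalues and are dropped before classification, leaving the
#' 30-column raw subset (5 per region).  Idempotent.
#'
#' @param x DTI features (matrix, data.frame, or [FeatureTable]).
#' @return numeric matrix with the 30 raw columns, region order
#'   preserved.
#' @export
dtiFeatureSubset <- function(x) {
  m <- .featureMatrix(x)
  keep <- as.vector(t(outer(.DTI_ROIS, .DTI_RAW, paste, sep = "_")))
  missing <- setdiff(keep, colnames(m))
  if (length(missing))
    stop("expected DTI column(s) missing: ", paste(missing, collapse = ", "))
  m[, keep, drop = FALSE]
}

#' Columns used as DTI regressors in cross-assessment regression
#'
#' All 48 DTI features except the perpendicular diffusivity of each
#' region (42 columns).
#'
#' @param x DTI features (matrix, data.frame, or [FeatureTable]).
#' @return numeric matrix with 42 columns.
#' @export
dtiRegressorSubset <- function(x) {
  m <- .featureMatrix(x)
  keep <- as.vector(t(outer(.DTI_ROIS,
                            c(.DTI_RAW, c("FA", "MD")), paste, sep = "_")))
  missing <- setdiff(keep, colnames(m))
  if (length(missing))
    stop("expected DTI column(s) missing: ", paste(missing, collapse = ", "))
  m[, keep, drop = FALSE]
}

setMethod("show", "RFEResult", function(object) {
  tr <- object@trajectory
  cat(sprintf("RFEResult: %d iterations, selected %d feature(s) at LOO accuracy %.4f\n",
              nrow(tr), length(object@selectedFeatures),
              tr$looAccuracy[object@selectedIteration]))
  w <- sort(abs(object@normalizedWeights), decreasing = TRUE)
  cat("  top features:",
      paste(sprintf("%s (%.3f)", names(head(w, 5)), head(w, 5)),
            collapse = ", "), "\n")
})
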
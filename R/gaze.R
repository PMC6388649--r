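# natural-viewing pipeline: trace extraction, dimension filtering, and
# the two-layer snippet classifier

#' Extract an attentional eye trace from saliency maps and gaze samples
#'
#' For every gaze sample, looks up the per-frame z-scored saliency value
#' at the gaze location in each channel's map, producing one standardized
#' 10-vector (or however many channels are supplied) per sample.
#' Constant maps z-score to 0; gaze samples outside the map produce
#' `NA` rows.
#'
#' @param maps named list over channels; each channel a list of frame
#'   matrices (rows = y, cols = x), or a single matrix for a static map.
#' @param gaze data.frame with columns `frame`, `x`, `y` (pixel indices).
#' @return samples x channels numeric matrix (an attentional eye trace).
#' @examples
#' m <- outer(dnorm(1:21, 11, 3), dnorm(1:21, 11, 3))
#' tr <- extractAttentionalTrace(list(C = m),
#'                               data.frame(frame = 1, x = 11, y = 11))
#' tr[1, "C"]   # the map's maximum z-score
#' @export
extractAttentionalTrace <- function(maps, gaze) {
  stopifnot(is.list(maps), length(maps) > 0,
            all(c("frame", "x", "y") %in% names(gaze)))
  maps <- lapply(maps, function(ch) if (is.matrix(ch)) list(ch) else ch)
  for (ch in maps) {
    for (fr in ch) {
      if (!is.matrix(fr) || length(fr) == 0) stop("empty saliency map")
    }
  }
  zmaps <- lapply(maps, function(ch) lapply(ch, .zscoreMap))
  n <- nrow(gaze)
  out <- matrix(NA_real_, n, length(maps),
                dimnames = list(NULL, names(maps)))
  for (i in seq_len(n)) {
    for (c in seq_along(zmaps)) {
      frames <- zmaps[[c]]
      f <- min(max(1L, as.integer(gaze$frame[i])), length(frames))
      mp <- frames[[f]]
      x <- as.integer(gaze$x[i]); y <- as.integer(gaze$y[i])
      if (!is.na(x) && !is.na(y) &&
          x >= 1 && x <= ncol(mp) && y >= 1 && y <= nrow(mp)) {
        out[i, c] <- mp[y, x]
      }
    }
  }
  out
}

.zscoreMap <- function(m) {
  s <- sd(as.vector(m))
  if (s == 0 || !is.finite(s)) return(m * 0)
  (m - mean(m)) / s
}

#' Two-sample t-test dimension filter with Bonferroni correction
#'
#' Per dimension, a two-tailed Welch two-sample t-test between groups;
#' dimensions whose p-value is not below `alpha / m` are dropped.
#' Dimensions with zero variance in both groups and equal means are
#' dropped with a warning (no group information).
#'
#' @param x numeric matrix (participants x dimensions).
#' @param y group labels.
#' @param alpha family-wise level (default 0.05).
#' @param m number of comparisons for the Bonferroni correction
#'   (default `ncol(x)`; pass a larger m when the family spans several
#'   blocks).
#' @return list: `keep` logical mask, `pvalue` per dimension,
#'   `threshold` the per-test level `alpha / m`.
#' @export
tTestFilter <- function(x, y, alpha = 0.05, m = ncol(x)) {
  x <- .featureMatrix(x)
  f <- .groupFactor(y)
  if (nlevels(droplevels(f)) < 2) stop("both classes must be present")
  a <- x[f == "FASD", , drop = FALSE]
  b <- x[f == "control", , drop = FALSE]
  na <- nrow(a); nb <- nrow(b)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- apply(a, 2, var); vb <- apply(b, 2, var)
  se2 <- va / na + vb / nb
  p <- numeric(ncol(x))
  zero <- se2 == 0
  if (any(zero)) {
    p[zero] <- ifelse(ma[zero] == mb[zero], 1, 0)
    if (any(zero & ma == mb))
      warning("dropping ", sum(zero & ma == mb),
              " zero-variance dimension(s)")
  }
  ok <- !zero
  if (any(ok)) {
    tt <- (ma[ok] - mb[ok]) / sqrt(se2[ok])
    df <- se2[ok]^2 / ((va[ok] / na)^2 / (na - 1) +
                         (vb[ok] / nb)^2 / (nb - 1))
    p[ok] <- 2 * pt(-abs(tt), df)
  }
  thr <- alpha / m
  list(keep = p < thr, pvalue = p, threshold = thr)
}

#' Train the two-layer natural-viewing classifier
#'
#' Stage one fits, per video snippet, an L1-regularized logistic weak
#' classifier on that snippet's (normalized, t-test-filtered)
#' representation; out-of-fold leave-one-out probabilities of FASD are
#' assembled into one vector per participant (one entry per snippet).
#' Stage two fits an L1-logistic classifier on those probability
#' vectors, with its C chosen by leave-one-out over a grid; the
#' snippets with non-zero second-layer coefficients are the selected
#' snippets.  The reported `finalProb` and `looAccuracy` are honest
#' leave-one-out quantities of the full stack.
#'
#' @param reps list over snippets of participant x dimension
#'   representation matrices (e.g. from [encodeCohortTraces()]); `NA`
#'   rows (missing snippets) are imputed with the training mean.
#' @param y group labels, one per participant.
#' @param alpha family-wise level of the t-test filter; the Bonferroni
#'   family is all dimensions across all snippets.
#' @param weakC loss weight of the snippet-level weak classifiers.
#' @param cGrid C grid for the second layer.
#' @return a [TwoLayerResult].
#' @export
twoLayerClassify <- function(reps, y, alpha = 0.05, weakC = 1,
                             cGrid = c(0.01, 0.1, 1, 10, 100)) {
  stopifnot(is.list(reps), length(reps) >= 1)
  f <- .groupFactor(y)
  if (min(table(f)) < 2) stop("need at least 2 participants per class")
  nS <- length(reps)
  n <- nrow(reps[[1]])
  totalDims <- sum(vapply(reps, ncol, integer(1)))

  minmax <- masks <- meanRep <- weakModels <- vector("list", nS)
  snippetProbs <- matrix(NA_real_, n, nS)
  for (s in seq_len(nS)) {
    x <- .featureMatrix(reps[[s]])
    # impute missing snippets with the training mean, per dimension
    mu <- colMeans(x, na.rm = TRUE)
    mu[!is.finite(mu)] <- 0
    for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- mu[j]
    meanRep[[s]] <- mu
    mm <- fitMinMax(x)
    xn <- applyMinMax(mm, x)
    flt <- suppressWarnings(tTestFilter(xn, f, alpha = alpha,
                                        m = totalDims))
    minmax[[s]] <- mm
    masks[[s]] <- flt$keep
    xs <- xn[, flt$keep, drop = FALSE]
    xfit <- if (ncol(xs) == 0) matrix(0, n, 1) else xs
    weakModels[[s]] <- fitL1LogReg(xfit, f, C = weakC)
    snippetProbs[, s] <- .weakOOF(xs, f, weakC)
  }

  sel <- chooseL1C(snippetProbs, f, grid = cGrid)
  second <- fitL1LogReg(snippetProbs, f, C = sel$C)
  finalProb <- sel$oofProb
  looAcc <- mean((finalProb > 0.5) == (f == "FASD"))
  new("TwoLayerResult",
      weakModels = weakModels, minmax = minmax, masks = masks,
      meanRep = meanRep, snippetProbs = snippetProbs,
      secondLayer = second, finalProb = finalProb, looAccuracy = looAcc,
      selectedSnippets = which(second@weights != 0))
}

# out-of-fold LOO probabilities of one weak classifier; an empty design
# falls back to the intercept-only fit (base-rate probability)
.weakOOF <- function(xs, f, weakC) {
  n <- length(f)
  if (ncol(xs) == 0) {
    m0 <- fitL1LogReg(matrix(0, n, 1), f, C = weakC)
    return(rep(.sigmoid(m0@intercept), n))
  }
  full <- fitL1LogReg(xs, f, C = weakC)
  st <- list(w = full@weights, b = full@intercept)
  vapply(seq_len(n), function(i) {
    m <- fitL1LogReg(xs[-i, , drop = FALSE], f[-i], C = weakC, start = st)
    predictProb(m, xs[i, , drop = FALSE])
  }, numeric(1))
}

#' @describeIn predictProb final FASD probability of new participants
#'   through the trained two-layer stack; `x` is a list over snippets of
#'   representation matrices aligned with the training snippets.
#' @export
setMethod("predictProb", "TwoLayerResult", function(object, x) {
  stopifnot(is.list(x), length(x) == length(object@weakModels))
  nS <- length(x)
  n <- nrow(x[[1]])
  probs <- matrix(NA_real_, n, nS)
  for (s in seq_len(nS)) {
    xs <- .featureMatrix(x[[s]])
    mu <- object@meanRep[[s]]
    for (j in seq_len(ncol(xs))) xs[is.na(xs[, j]), j] <- mu[j]
    xn <- applyMinMax(object@minmax[[s]], xs)
    xk <- xn[, object@masks[[s]], drop = FALSE]
    wm <- object@weakModels[[s]]
    if (ncol(xk) == 0 || length(wm@weights) != ncol(xk)) {
      probs[, s] <- .sigmoid(wm@intercept)
    } else {
      probs[, s] <- predictProb(wm, xk)
    }
  }
  predictProb(object@secondLayer, probs)
})

setMethod("show", "TwoLayerResult", function(object) {
  cat(sprintf("TwoLayerResult: %d snippets, %d selected, LOO accuracy %.4f\n",
              ncol(object@snippetProbs), length(object@selectedSnippets),
              object@looAccuracy))
})
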
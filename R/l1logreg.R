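# L1-regularized logistic regression
#
# Minimizes  sum_j |w_j| + C * sum_i log(1 + exp(-y_i (x_i' w + b)))
# with labels y_i = +1 (FASD) / -1 (control) and an optional unpenalized
# intercept b.  The nonsmooth penalty is handled by the positive/negative
# split w = u - v, u, v >= 0, which turns the problem into a smooth
# bound-constrained one solved with L-BFGS-B; coefficients whose parts
# both sit on the bound are exactly zero.

.l1Objective <- function(w, b, x, ypm, C) {
  z <- drop(x %*% w) + b
  sum(abs(w)) + C * sum(.log1pexpNeg(ypm * z))
}

#' Fit an L1-regularized logistic classifier
#'
#' @param x numeric matrix of inputs (participants in rows), already
#'   normalized to the 0-1 range across participants.
#' @param y group labels: `control`/`FASD` factor, or 0/1, or -1/+1
#'   (positive = FASD).
#' @param C loss weight (larger C = weaker regularization); must be
#'   positive.
#' @param intercept include an unpenalized intercept (default `TRUE`).
#' @param start optional warm start `list(w =, b =)`.
#' @return an [L1LogRegModel].
#' @examples
#' set.seed(1)
#' x <- matrix(runif(40), 20, 2)
#' y <- as.integer(x[, 1] + 0.2 * rnorm(20) > 0.5)
#' m <- fitL1LogReg(x, y, C = 5)
#' coef(m)
#' @export
fitL1LogReg <- function(x, y, C, intercept = TRUE, start = NULL) {
  if (C <= 0) stop("C must be positive")
  x <- .featureMatrix(x)
  ypm <- .toPM(y)
  stopifnot(length(ypm) == nrow(x))
  p <- ncol(x)
  nb <- if (intercept) 1L else 0L
  par0 <- numeric(2 * p + nb)
  if (!is.null(start)) {
    par0[seq_len(p)] <- pmax(start$w, 0)
    par0[p + seq_len(p)] <- pmax(-start$w, 0)
    if (intercept) par0[2 * p + 1] <- start$b
  }
  fn <- function(par) {
    w <- par[seq_len(p)] - par[p + seq_len(p)]
    b <- if (intercept) par[2 * p + 1] else 0
    sum(par[seq_len(2 * p)]) + C * sum(.log1pexpNeg(ypm * (drop(x %*% w) + b)))
  }
  gr <- function(par) {
    w <- par[seq_len(p)] - par[p + seq_len(p)]
    b <- if (intercept) par[2 * p + 1] else 0
    z <- drop(x %*% w) + b
    s <- -ypm * .sigmoid(-ypm * z)      # d loss / d z
    g <- C * drop(crossprod(x, s))
    out <- c(1 + g, 1 - g)
    if (intercept) out <- c(out, C * sum(s))
    out
  }
  lower <- c(rep(0, 2 * p), if (intercept) -Inf)
  opt <- optim(par0, fn, gr, method = "L-BFGS-B", lower = lower,
               control = list(maxit = 2000, factr = 1e3))
  w <- opt$par[seq_len(p)] - opt$par[p + seq_len(p)]
  w[opt$par[seq_len(p)] == 0 & opt$par[p + seq_len(p)] == 0] <- 0
  b <- if (intercept) opt$par[2 * p + 1] else 0
  # note: the C slot is assigned after new(): a `C =` argument would
  # partially match new()'s Class formal
  m <- new("L1LogRegModel",
           weights = stats::setNames(w, colnames(x)), intercept = b,
           hasIntercept = intercept, objective = opt$value,
           converged = opt$convergence == 0)
  m@C <- C
  validObject(m)
  m
}

# labels to +1/-1
.toPM <- function(y) {
  if (is.factor(y) || is.character(y)) return(.pmLabels(y))
  y <- as.numeric(y)
  u <- sort(unique(y))
  if (all(u %in% c(0, 1))) return(ifelse(y > 0, 1, -1))
  if (all(u %in% c(-1, 1))) return(y)
  stop("labels must be control/FASD, 0/1, or -1/+1")
}

#' @describeIn predictProb probability of FASD under the logistic model.
#' @export
setMethod("predictProb", "L1LogRegModel", function(object, x) {
  x <- .featureMatrix(x)
  .sigmoid(drop(x %*% object@weights) + object@intercept)
})

#' @describeIn fitL1LogReg coefficients of a fitted model.
#' @param object an [L1LogRegModel].
#' @param ... ignored.
#' @export
setMethod("coef", "L1LogRegModel", function(object, ...) object@weights)

#' Objective value of an L1-logistic model on given data
#'
#' Evaluates `sum(|w|) + C * sum(log(1 + exp(-y * (x'w + b))))` for a
#' fitted model, mainly for optimizer cross-checks.
#'
#' @param model an [L1LogRegModel].
#' @param x,y the data the model was fit on.
#' @return objective value.
#' @export
l1Objective <- function(model, x, y) {
  .l1Objective(model@weights, model@intercept, .featureMatrix(x),
               .toPM(y), model@C)
}

#' Choose C by leave-one-out cross-validation
#'
#' @param x,y training data as in [fitL1LogReg()].
#' @param grid candidate values of C.
#' @param intercept passed to [fitL1LogReg()].
#' @return list: `C` (best value; accuracy ties resolved toward the
#'   smaller, sparser C), `accuracy` per grid value, and `oofProb`
#'   out-of-fold probabilities at the chosen C.
#' @export
chooseL1C <- function(x, y, grid = c(0.01, 0.1, 1, 10, 100),
                      intercept = TRUE) {
  x <- .featureMatrix(x)
  ypm <- .toPM(y)
  n <- nrow(x)
  acc <- numeric(length(grid))
  oof <- matrix(NA_real_, n, length(grid))
  for (g in seq_along(grid)) {
    warm <- fitL1LogReg(x, ypm, grid[g], intercept = intercept)
    st <- list(w = warm@weights, b = warm@intercept)
    for (i in seq_len(n)) {
      m <- fitL1LogReg(x[-i, , drop = FALSE], ypm[-i], grid[g],
                       intercept = intercept, start = st)
      oof[i, g] <- predictProb(m, x[i, , drop = FALSE])
    }
    acc[g] <- mean((oof[, g] > 0.5) == (ypm > 0))
  }
  best <- which(acc == max(acc))[1]    # grid ordered ascending: sparser C
  list(C = grid[best], accuracy = stats::setNames(acc, grid),
       oofProb = oof[, best])
}

setMethod("show", "L1LogRegModel", function(object) {
  nz <- sum(object@weights != 0)
  cat(sprintf("L1LogRegModel: C = %g, %d/%d non-zero weights, objective %.4f\n",
              object@C, nz, length(object@weights), object@objective))
})
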
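# topographic ICA feature learning on attentional eye traces
#
# Per saliency channel, two stacked TICA layers.  Each layer whitens its
# input windows (uncentered PCA whitening: traces are standardized, so
# encoding stays linear and a zero trace encodes to zero) and learns a
# square orthonormal filter bank W minimizing the topographic sparse
# objective
#
#   J(W) = mean_n  sum_q  sqrt(eps + sum_{i in pool q} (W z_n)_i^2)
#
# where the pools q are 2x2 neighborhoods (with wrap-around) of the
# filters arranged on a torus map.  Optimization is projected gradient
# descent with backtracking: after each step W is retracted onto the
# orthogonal manifold by symmetric orthogonalization, and a step is only
# accepted if the objective does not increase, so the recorded objective
# trajectory is non-increasing.

#' Default TICA geometry
#'
#' 32 filters on 32-sample windows (50% overlap), filters arranged on an
#' 8 x 4 torus map with 2 x 2 pooling, identical geometry in both layers.
#' The filter bank is square so that row-orthonormality is attainable in
#' the whitened space.
#'
#' @param windowLen samples per first-layer window.
#' @param mapDim filters map (rows, cols); `prod(mapDim)` filters.
#' @param poolSize pooling neighborhood.
#' @param eps smoothing inside the square root during training.
#' @param maxit,tol optimizer budget and relative-decrease stop.
#' @return config list for [trainTICA()].
#' @export
ticaConfig <- function(windowLen = 32L, mapDim = c(8L, 4L),
                       poolSize = c(2L, 2L), eps = 1e-4,
                       maxit = 200L, tol = 1e-6) {
  k <- prod(mapDim)
  if (k > windowLen)
    stop("mapDim implies more filters than window dimensions; ",
         "orthonormal rows are infeasible")
  list(windowLen = as.integer(windowLen), mapDim = as.integer(mapDim),
       poolSize = as.integer(poolSize), nFilters = as.integer(k),
       eps = eps, maxit = as.integer(maxit), tol = tol)
}

# pool membership matrix (pools x filters) on a torus map
.poolMatrix <- function(mapDim, poolSize) {
  r <- mapDim[1]; cc <- mapDim[2]
  k <- r * cc
  P <- matrix(0, k, k)
  for (i in seq_len(r)) {
    for (j in seq_len(cc)) {
      q <- (j - 1) * r + i
      for (di in seq_len(poolSize[1]) - 1) {
        for (dj in seq_len(poolSize[2]) - 1) {
          ii <- (i - 1 + di) %% r + 1
          jj <- (j - 1 + dj) %% cc + 1
          P[q, (jj - 1) * r + ii] <- 1
        }
      }
    }
  }
  P
}

# symmetric orthogonalization: rows of W become orthonormal
.symOrth <- function(W) {
  s <- svd(W)
  s$u %*% t(s$v)
}

# uncentered PCA whitening matrix (k x d): V %*% x has identity second
# moment in the k leading directions
.whitenMatrix <- function(X, k) {
  C <- tcrossprod(X) / ncol(X)
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values[seq_len(k)], 1e-12)
  diag(1 / sqrt(ev), k) %*% t(e$vectors[, seq_len(k), drop = FALSE])
}

# train one TICA layer on windows X (d x N); returns layer list
.trainTICALayer <- function(X, config) {
  k <- config$nFilters
  if (ncol(X) < k) stop("not enough training windows for the layer")
  V <- .whitenMatrix(X, k)
  Z <- V %*% X
  P <- .poolMatrix(config$mapDim, config$poolSize)
  W <- .symOrth(matrix(rnorm(k * k), k, k))
  objective <- function(W) {
    S <- W %*% Z
    mean(colSums(sqrt(config$eps + P %*% S^2)))
  }
  gradient <- function(W) {
    S <- W %*% Z
    pooled <- sqrt(config$eps + P %*% S^2)
    R <- crossprod(P, 1 / pooled)
    ((S * R) %*% t(Z)) / ncol(Z)
  }
  obj <- objective(W)
  trace <- obj
  step <- 0.5
  for (it in seq_len(config$maxit)) {
    G <- gradient(W)
    accepted <- FALSE
    for (try in 1:30) {
      Wn <- .symOrth(W - step * G)
      objn <- objective(Wn)
      if (objn <= obj) { accepted <- TRUE; break }
      step <- step / 2
    }
    if (!accepted) break
    improved <- obj - objn
    W <- Wn
    obj <- objn
    trace <- c(trace, obj)
    step <- min(step * 1.2, 10)
    if (improved < config$tol * max(abs(obj), 1)) break
  }
  list(whiten = V, W = W, pool = P, objectiveTrace = trace)
}

# slice a trace column (vector) into windows with 50% overlap -> d x nwin
.windows <- function(v, len) {
  n <- length(v)
  if (n < len) stop("trace shorter than the window length")
  hop <- max(1L, len %/% 2L)
  starts <- seq(1L, n - len + 1L, by = hop)
  vapply(starts, function(s) v[s:(s + len - 1L)], numeric(len))
}

#' Train a two-layer TICA network on attentional eye traces
#'
#' One two-layer network is learned per saliency channel, so that the
#' representation keeps channels separate until concatenation.  The
#' first layer sees raw trace windows; the second layer sees the
#' first layer's pooled activation vectors.
#'
#' @param traces list over participants of lists of snippet matrices
#'   (samples x channels), as produced by [generateAttentionalTraces()]
#'   or [cohortTraces()]; a flat list of matrices is also accepted.
#' @param config geometry from [ticaConfig()].
#' @param channels channel names to model (default: all 10).
#' @param seed RNG seed for filter initialization.
#' @return a trained [TICANetwork].
#' @export
trainTICA <- function(traces, config = ticaConfig(),
                      channels = .TRACE_CHANNELS, seed = 1L) {
  flat <- .flattenTraces(traces)
  set.seed(as.integer(seed))
  layers <- lapply(channels, function(ch) {
    X <- do.call(cbind, lapply(flat, function(tr)
      .windows(tr[, ch], config$windowLen)))
    if (ncol(X) < 100) stop("need at least 100 training windows per channel")
    l1 <- .trainTICALayer(X, config)
    A1 <- sqrt(config$eps + l1$pool %*% (l1$W %*% (l1$whiten %*% X))^2)
    l2 <- .trainTICALayer(A1, config)
    list(l1, l2)
  })
  names(layers) <- channels
  net <- new("TICANetwork", channels = channels, layers = layers,
             config = config, trained = TRUE)
  validObject(net)
  net
}

.flattenTraces <- function(traces) {
  if (is(traces, "SimpleList")) traces <- as.list(traces)
  if (is.matrix(traces)) return(list(traces))
  if (!is.list(traces) || !length(traces))
    stop("traces must be a matrix, a list of matrices, or a list of such lists")
  if (is.matrix(traces[[1]])) return(traces)
  unlist(traces, recursive = FALSE)
}

# encode windows of one channel through both layers; returns pooled
# second-layer activations (k x nwin).  Encoding uses the exact sqrt of
# pooled energy (no eps), so a zero input encodes to exactly zero and
# first-layer responses are linear in the input amplitude.
.encodeChannel <- function(lys, v, config) {
  X <- .windows(v, config$windowLen)
  S1 <- lys[[1]]$W %*% (lys[[1]]$whiten %*% X)
  A1 <- sqrt(lys[[1]]$pool %*% S1^2)
  S2 <- lys[[2]]$W %*% (lys[[2]]$whiten %*% A1)
  sqrt(lys[[2]]$pool %*% S2^2)
}

#' @describeIn encodeTrace mean-pooled two-layer activations per channel,
#'   concatenated across channels into one fixed-length vector.
#' @export
setMethod("encodeTrace", "TICANetwork", function(net, trace) {
  if (!net@trained) stop("network is not trained")
  stopifnot(is.matrix(trace))
  out <- lapply(net@channels, function(ch) {
    rowMeans(.encodeChannel(net@layers[[ch]], trace[, ch], net@config))
  })
  v <- unlist(out)
  names(v) <- as.vector(t(outer(net@channels,
                                seq_len(net@config$nFilters),
                                paste, sep = ".u")))
  v
})

#' Encode many participants' snippet traces
#'
#' @param net a trained [TICANetwork].
#' @param traces named list over participants; each element a list of
#'   snippet matrices.
#' @return list over snippets of participant x dimension matrices
#'   (representation per snippet), participant names preserved.
#' @export
encodeCohortTraces <- function(net, traces) {
  if (is(traces, "SimpleList")) traces <- as.list(traces)
  stopifnot(length(traces) > 0)
  nS <- length(traces[[1]])
  ids <- names(traces) %||% sprintf("P%03d", seq_along(traces))
  lapply(seq_len(nS), function(s) {
    m <- t(vapply(traces, function(tr) encodeTrace(net, tr[[s]]),
                  numeric(length(net@channels) * net@config$nFilters)))
    rownames(m) <- ids
    m
  })
}

#' Objective trajectory of a trained TICA layer
#'
#' @param net a [TICANetwork].
#' @param channel channel name.
#' @param layer 1 or 2.
#' @return numeric vector of accepted objective values (non-increasing).
#' @export
ticaObjectiveTrace <- function(net, channel, layer = 1) {
  net@layers[[channel]][[layer]]$objectiveTrace
}

setMethod("show", "TICANetwork", function(object) {
  cat(sprintf("TICANetwork: %d channel(s), 2 layers, %d filters on %dx%d torus, window %d\n",
              length(object@channels), object@config$nFilters,
              object@config$mapDim[1], object@config$mapDim[2],
              object@config$windowLen))
})
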
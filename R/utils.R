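# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half-up to a fixed number of decimals
#'
#' Report convention for percentages: round half away from zero, so
#' 81.825 prints as 81.83 rather than banker's 81.82.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 2).
#' @return rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Truncate a dollar amount to whole dollars
#'
#' Monetary results are reported truncated toward zero (9933.16 reports
#' as 9933).
#'
#' @param x numeric dollar amounts.
#' @return integer-valued numeric.
#' @export
wholeDollars <- function(x) trunc(x)

# numerically stable log(1 + exp(-t)) for the logistic loss
.log1pexpNeg <- function(t) {
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- log1p(exp(-t[pos]))
  out[!pos] <- -t[!pos] + log1p(exp(t[!pos]))
  out
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

# canonical group factor: control first (negative class), FASD positive
.groupFactor <- function(x) {
  f <- factor(as.character(x), levels = c("control", "FASD"))
  if (anyNA(f)) {
    stop("group labels must be 'control' or 'FASD'; got: ",
         paste(unique(setdiff(as.character(x), c("control", "FASD"))),
               collapse = ", "))
  }
  f
}

# labels as +1 (FASD) / -1 (control)
.pmLabels <- function(y) {
  f <- .groupFactor(y)
  ifelse(f == "FASD", 1, -1)
}

# coerce a features input (matrix / data.frame / FeatureTable) to a
# numeric matrix with participants in rows
.featureMatrix <- function(x) {
  if (is(x, "FeatureTable")) return(featureMatrix(x))
  if (is.data.frame(x)) {
    num <- vapply(x, is.numeric, logical(1))
    x <- as.matrix(x[, num, drop = FALSE])
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expected a numeric matrix, data.frame, or FeatureTable")
  }
  if (is.null(colnames(x))) {
    colnames(x) <- sprintf("V%d", seq_len(ncol(x)))
  }
  x
}

# md5 of a serialized R object (config provenance); base tools only
.objectHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

# deterministic child seed below 2^31, derived from a base seed and a tag
.childSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 69069 + h * 7919) %% .Machine$integer.max)
}
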
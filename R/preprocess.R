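# train-referenced normalization and age correction

#' @rdname fitMinMax
#' @export
setMethod("fitMinMax", "matrix", function(x) {
  x <- .featureMatrix(x)
  if (nrow(x) < 2) stop("need at least 2 participants to fit normalization")
  mins <- apply(x, 2, min)
  maxs <- apply(x, 2, max)
  new("MinMaxModel", features = colnames(x), min = mins, max = maxs,
      degenerate = maxs == mins)
})

#' @rdname fitMinMax
#' @export
setMethod("fitMinMax", "data.frame", function(x) {
  fitMinMax(.featureMatrix(x))
})

#' @rdname fitMinMax
#' @export
setMethod("fitMinMax", "FeatureTable", function(x) {
  fitMinMax(featureMatrix(x))
})

.applyMinMaxMatrix <- function(model, x) {
  x <- .featureMatrix(x)
  missing <- setdiff(model@features, colnames(x))
  if (length(missing))
    stop("features absent from data: ", paste(missing, collapse = ", "))
  unknown <- setdiff(colnames(x), model@features)
  if (length(unknown))
    stop("unknown feature name(s): ", paste(unknown, collapse = ", "))
  x <- x[, model@features, drop = FALSE]
  rng <- model@max - model@min
  rng[model@degenerate] <- 1          # avoid 0/0; output forced to 0 below
  out <- sweep(sweep(x, 2, model@min, "-"), 2, rng, "/")
  out[, model@degenerate] <- 0
  out
}

#' @rdname applyMinMax
#' @export
setMethod("applyMinMax", signature("MinMaxModel", "ANY"),
          function(model, x) .applyMinMaxMatrix(model, x))

#' Serialize a normalization model to JSON
#'
#' @param model a [MinMaxModel].
#' @param path optional file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
minMaxToJSON <- function(model, path = NULL) {
  obj <- list(features = model@features,
              min = unname(model@min), max = unname(model@max),
              degenerate = unname(model@degenerate))
  js <- jsonlite::toJSON(obj, auto_unbox = FALSE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read a normalization model from JSON
#'
#' @param path file written by [minMaxToJSON()].
#' @return a [MinMaxModel].
#' @export
minMaxFromJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("MinMaxModel", features = obj$features,
      min = stats::setNames(obj$min, obj$features),
      max = stats::setNames(obj$max, obj$features),
      degenerate = stats::setNames(obj$degenerate, obj$features))
}

setMethod("show", "MinMaxModel", function(object) {
  cat(sprintf("MinMaxModel: %d features (%d degenerate)\n",
              length(object@features), sum(object@degenerate)))
})

#' Control-referenced linear age correction
#'
#' For every feature, fits an ordinary least-squares line `feature ~ age`
#' on the reference rows (typically the typically-developing controls of
#' the training set) and subtracts the fitted, centered age component
#' `slope * (age - mean(reference age))` from all rows.  Group contrasts
#' that are not age-driven are preserved.
#'
#' @param x features (matrix, data.frame, or [FeatureTable]),
#'   participants in rows.
#' @param age ages in years for every row.
#' @param referenceRows indices (or logical) of the rows used to fit the
#'   age line; at least 3 with non-constant age.
#' @return numeric matrix of corrected features, same shape and names.
#' @examples
#' set.seed(1)
#' age <- runif(50, 5, 18)
#' x <- cbind(f1 = 2 * age + rnorm(50))
#' cor(ageCorrect(x, age, 1:50)[, 1], age)   # ~ 0
#' @export
ageCorrect <- function(x, age, referenceRows) {
  x <- .featureMatrix(x)
  stopifnot(length(age) == nrow(x))
  ref <- seq_len(nrow(x))[referenceRows]
  if (length(ref) < 3) stop("need at least 3 reference rows")
  aref <- age[ref]
  if (diff(range(aref)) == 0)
    stop("reference ages are all equal; age slope is unidentifiable")
  ac <- aref - mean(aref)
  slope <- drop(crossprod(ac, x[ref, , drop = FALSE])) / sum(ac^2)
  x - outer(age - mean(aref), slope)
}
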
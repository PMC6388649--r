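# FeatureTable construction and accessors

#' Build a FeatureTable from a participants-by-features matrix
#'
#' @param features numeric matrix or data.frame, participants in rows,
#'   named feature columns.
#' @param group participant group labels (`control` / `FASD`).
#' @param age ages in years.
#' @param sex optional, `M` / `F`.
#' @param id optional participant identifiers (default row names or
#'   `P001`...).
#' @param assessment assessment name stored in `metadata()`.
#' @return a [FeatureTable].
#' @examples
#' ft <- featureTable(matrix(rnorm(20), 5, 4,
#'                           dimnames = list(NULL, paste0("f", 1:4))),
#'                    group = c("FASD", "FASD", "control", "control",
#'                              "control"),
#'                    age = c(9, 12, 10, 8, 14))
#' featureMatrix(ft)
#' @export
featureTable <- function(features, group, age, sex = NULL, id = NULL,
                         assessment = "assessment") {
  m <- .featureMatrix(features)
  n <- nrow(m)
  group <- .groupFactor(group)
  stopifnot(length(group) == n, length(age) == n)
  if (is.null(id)) id <- rownames(m) %||% sprintf("P%03d", seq_len(n))
  cd <- S4Vectors::DataFrame(group = group, age = as.numeric(age),
                             row.names = id)
  if (!is.null(sex)) cd$sex <- factor(sex, levels = c("F", "M"))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(m)), colData = cd)
  rownames(se) <- colnames(m)
  out <- new("FeatureTable", se)
  S4Vectors::metadata(out)$assessment <- assessment
  validObject(out)
  out
}

#' @rdname featureMatrix
#' @export
setMethod("featureMatrix", "FeatureTable", function(x) {
  t(SummarizedExperiment::assay(x, "features"))
})

#' @rdname groups
#' @export
setMethod("groups", "FeatureTable", function(x) {
  .groupFactor(SummarizedExperiment::colData(x)$group)
})

#' @rdname ages
#' @export
setMethod("ages", "FeatureTable", function(x) {
  as.numeric(SummarizedExperiment::colData(x)$age)
})

#' Assessment name of a FeatureTable
#'
#' @param x a [FeatureTable].
#' @return character scalar.
#' @export
assessmentName <- function(x) {
  stopifnot(is(x, "FeatureTable"))
  S4Vectors::metadata(x)$assessment %||% "assessment"
}

setMethod("show", "FeatureTable", function(object) {
  g <- groups(object)
  cat(sprintf("FeatureTable '%s': %d features x %d participants (%d FASD, %d control)\n",
              assessmentName(object), nrow(object), ncol(object),
              sum(g == "FASD"), sum(g == "control")))
})
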
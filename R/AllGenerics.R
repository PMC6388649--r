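# generics

#' Extract the participants-by-features matrix of a FeatureTable
#'
#' @param x a [FeatureTable].
#' @return numeric matrix, participants in rows, features in columns.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' Group labels of a FeatureTable or cohort
#'
#' @param x a [FeatureTable] or [FASDCohort].
#' @return factor with levels `control`, `FASD`.
#' @export
setGeneric("groups", function(x) standardGeneric("groups"))

#' Ages (years) of the participants
#'
#' @param x a [FeatureTable] or [FASDCohort].
#' @return numeric vector.
#' @export
setGeneric("ages", function(x) standardGeneric("ages"))

#' Fit a train-referenced min-max normalization model
#'
#' Stores each feature's training minimum and maximum so that training
#' data maps onto the 0-1 range within every feature dimension.
#'
#' @param x training features: matrix, data.frame, or [FeatureTable]
#'   (participants in rows).
#' @return a [MinMaxModel].
#' @export
setGeneric("fitMinMax", function(x) standardGeneric("fitMinMax"))

#' Apply a min-max normalization model
#'
#' Maps `(x - min) / (max - min)` feature-wise using the *training*
#' extrema.  Test values outside the training range fall outside
#' \[0, 1\] and are deliberately not clipped; degenerate (constant in
#' training) features map to 0.
#'
#' @param model a [MinMaxModel].
#' @param x features to normalize; must contain every model feature.
#' @return numeric matrix of normalized features in model feature order.
#' @export
setGeneric("applyMinMax", function(model, x) standardGeneric("applyMinMax"))

#' Train an SVM-RFE classifier on one assessment
#'
#' @param x normalized training features (matrix or [FeatureTable]).
#' @param ... passed to methods; see [rfeTrain,matrix-method].
#' @return an [RFEResult].
#' @export
setGeneric("rfeTrain", function(x, ...) standardGeneric("rfeTrain"))

#' Predict FASD probabilities from a trained model
#'
#' @param object a trained model ([RFEResult], [L1LogRegModel],
#'   [TwoLayerResult]).
#' @param x new data in the representation the model was trained on
#'   (already normalized with the training normalization model).
#' @param ... method-specific arguments.
#' @return numeric vector of probabilities of FASD in \[0, 1\].
#' @export
setGeneric("predictProb", function(object, x, ...)
  standardGeneric("predictProb"))

#' Encode an attentional eye trace through a trained TICA network
#'
#' @param net a trained [TICANetwork].
#' @param trace samples x channels numeric matrix (one video snippet).
#' @return numeric representation vector (channels x pooled units).
#' @export
setGeneric("encodeTrace", function(net, trace) standardGeneric("encodeTrace"))

#' Expected annual value of the screening decision tree
#'
#' @param scenario a [ScreeningScenario].
#' @return expected value in dollars per screened individual per year.
#' @export
setGeneric("expectedValue", function(scenario)
  standardGeneric("expectedValue"))
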
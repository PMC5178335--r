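#' @include AllClasses.R
NULL

#' Number of mixture components
#' @param object a [GmmParams-class].
#' @export
setGeneric("nComponents", function(object) standardGeneric("nComponents"))

#' @describeIn nComponents component count of a mixture.
#' @export
setMethod("nComponents", "GmmParams", function(object) length(object@weights))

#' Feature dimensionality of a model or feature set
#' @param object a [GmmParams-class] or [FeatureSet-class].
#' @export
setGeneric("featureDim", function(object) standardGeneric("featureDim"))

#' @describeIn featureDim dimension of a mixture model.
#' @export
setMethod("featureDim", "GmmParams", function(object) ncol(object@means))

#' @describeIn featureDim coefficient count of a feature set.
#' @export
setMethod("featureDim", "FeatureSet", function(object) {
  if (!length(object@features)) 0L else ncol(object@features[[1L]])
})

#' Mixture parameter accessors
#' @param object a [GmmParams-class].
#' @name gmm-accessors
NULL

#' @rdname gmm-accessors
#' @export
setGeneric("mixtureWeights", function(object) standardGeneric("mixtureWeights"))
#' @rdname gmm-accessors
#' @export
setMethod("mixtureWeights", "GmmParams", function(object) object@weights)
#' @rdname gmm-accessors
#' @export
setGeneric("mixtureMeans", function(object) standardGeneric("mixtureMeans"))
#' @rdname gmm-accessors
#' @export
setMethod("mixtureMeans", "GmmParams", function(object) object@means)
#' @rdname gmm-accessors
#' @export
setGeneric("mixtureVariances", function(object) standardGeneric("mixtureVariances"))
#' @rdname gmm-accessors
#' @export
setMethod("mixtureVariances", "GmmParams", function(object) object@variances)

#' Annotation table of a dataset
#' @param object a [SynthDataset-class].
#' @export
setGeneric("annotations", function(object) standardGeneric("annotations"))

#' @describeIn annotations annotation rows of a synthetic dataset.
#' @export
setMethod("annotations", "SynthDataset", function(object) object@annotations)

#' Feature-set accessors
#' @param object a [FeatureSet-class].
#' @name featureset-accessors
NULL

#' @rdname featureset-accessors
#' @export
setGeneric("vocFeatures", function(object) standardGeneric("vocFeatures"))
#' @rdname featureset-accessors
#' @export
setMethod("vocFeatures", "FeatureSet", function(object) object@features)
#' @rdname featureset-accessors
#' @export
setGeneric("vocMeta", function(object) standardGeneric("vocMeta"))
#' @rdname featureset-accessors
#' @export
setMethod("vocMeta", "FeatureSet", function(object) object@meta)

#' Balanced accuracy
#'
#' The confusion matrix is row-normalized by true-class size; balanced
#' accuracy is the mean of its diagonal, i.e. the average per-class recall.
#' Chance level for C equiprobable classes is 1/C regardless of class
#' imbalance.
#'
#' @param object a [ConfusionMatrix-class].
#' @return a fraction in \[0, 1\].
#' @export
setGeneric("balancedAccuracy", function(object) standardGeneric("balancedAccuracy"))

#' @describeIn balancedAccuracy mean of the row-normalized diagonal.
#' @export
setMethod("balancedAccuracy", "ConfusionMatrix", function(object) {
  mean(diag(rowNormalized(object)))
})

#' Row-normalized confusion matrix
#' @param object a [ConfusionMatrix-class].
#' @return C x C matrix whose rows sum to 1.
#' @export
setGeneric("rowNormalized", function(object) standardGeneric("rowNormalized"))

#' @describeIn rowNormalized each row divided by its true-class size.
#' @export
setMethod("rowNormalized", "ConfusionMatrix", function(object) {
  object@counts / rowSums(object@counts)
})

#' Per-class sizes of a confusion matrix
#' @param object a [ConfusionMatrix-class].
#' @export
setGeneric("classSizes", function(object) standardGeneric("classSizes"))

#' @describeIn classSizes row sums (true-class counts).
#' @export
setMethod("classSizes", "ConfusionMatrix", function(object) {
  setNames(rowSums(object@counts), object@labels)
})

#' Score matrix of cross-validated predictions
#'
#' Each test vocalization is represented by the vector of
#' log-likelihood-ratio scores it received for every candidate class; the
#' UBM has no column because scores are already ratios against it.
#'
#' @param object a [LooResult-class].
#' @return N x C numeric matrix, columns named by class.
#' @export
setGeneric("scoreMatrix", function(object) standardGeneric("scoreMatrix"))

#' @describeIn scoreMatrix the N x C held-out score matrix.
#' @export
setMethod("scoreMatrix", "LooResult", function(object) object@scores)

#' Predicted and true labels of a cross-validation run
#' @param object a [LooResult-class].
#' @name loo-accessors
NULL

#' @rdname loo-accessors
#' @export
setGeneric("predictedLabels", function(object) standardGeneric("predictedLabels"))
#' @rdname loo-accessors
#' @export
setMethod("predictedLabels", "LooResult", function(object) object@predicted)
#' @rdname loo-accessors
#' @export
setGeneric("trueLabels", function(object) standardGeneric("trueLabels"))
#' @rdname loo-accessors
#' @export
setMethod("trueLabels", "LooResult", function(object) object@truth)
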
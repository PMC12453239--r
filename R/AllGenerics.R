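#' @rdname SpectralDataset-class
#' @param object,x an object of the documented class
#' @param ... passed to methods
#' @export
setGeneric("wavenumbers", function(object) standardGeneric("wavenumbers"))

#' @rdname SpectralDataset-class
#' @export
setGeneric("absorbance", function(object) standardGeneric("absorbance"))

#' @rdname SpectralDataset-class
#' @export
setGeneric("replicateOf", function(object) standardGeneric("replicateOf"))

#' Sample annotations of a dataset
#'
#' @param object a \linkS4class{SpectralDataset}, \linkS4class{ProteinTable}
#'   or \linkS4class{FeatureMatrix}.
#' @return a \code{DataFrame} with \code{sample_id}, \code{class} and
#'   \code{pair_id}.
#' @export
setGeneric("sampleInfo", function(object) standardGeneric("sampleInfo"))

#' Binary class labels (FRI = 1, control = 0)
#'
#' @param object an annotated dataset object.
#' @return integer vector of 0/1 labels in sample order.
#' @export
setGeneric("classLabels", function(object) standardGeneric("classLabels"))

#' @rdname ProteinTable-class
#' @param object a \code{ProteinTable}
#' @export
setGeneric("ratios", function(object) standardGeneric("ratios"))

#' @rdname ProteinTable-class
#' @export
setGeneric("proteinIds", function(object) standardGeneric("proteinIds"))

#' @rdname FeatureMatrix-class
#' @param object a \code{FeatureMatrix}
#' @export
setGeneric("features", function(object) standardGeneric("features"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("featureIds", function(object) standardGeneric("featureIds"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("retainedIndices", function(object) standardGeneric("retainedIndices"))

#' Nonzero-coefficient feature ids of a fitted sparse model
#'
#' The elastic net's l1 component drives coefficients of uninformative
#' features to exactly zero; the surviving ids are the model's embedded
#' feature selection.
#'
#' @param object a fitted \linkS4class{ElasticNetModel}.
#' @return character vector of feature ids with nonzero coefficients
#'   (at most the model's \code{maxNonzero} cap).
#' @export
setGeneric("selectedFeatures", function(object) standardGeneric("selectedFeatures"))

#' Predicted positive-class probabilities
#'
#' @param object a fitted \linkS4class{ElasticNetModel}.
#' @param newdata numeric matrix or \linkS4class{FeatureMatrix} whose columns
#'   match the model's feature ids.
#' @return numeric vector of probabilities in (0, 1).
#' @export
setGeneric("predictProba", function(object, newdata) standardGeneric("predictProba"))

#' Pooled performance estimates as a data.frame
#'
#' @param object a \linkS4class{PooledMetrics}.
#' @return data.frame with metric, pooled mean, SD, CI95 bounds.
#' @export
setGeneric("pooledEstimates", function(object) standardGeneric("pooledEstimates"))
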
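# Accessors and show() methods for the S4 containers.

#' @rdname SpectralDataset-class
#' @export
setMethod("wavenumbers", "SpectralDataset", function(object) object@wavenumbers)

#' @rdname SpectralDataset-class
#' @export
setMethod("absorbance", "SpectralDataset", function(object) object@absorbance)

#' @rdname SpectralDataset-class
#' @export
setMethod("replicateOf", "SpectralDataset", function(object) object@replicateOf)

#' @rdname sampleInfo
#' @export
setMethod("sampleInfo", "SpectralDataset", function(object) object@samples)

#' @rdname sampleInfo
#' @export
setMethod("sampleInfo", "ProteinTable", function(object) object@samples)

#' @rdname sampleInfo
#' @export
setMethod("sampleInfo", "FeatureMatrix", function(object) object@samples)

.labelsFrom <- function(samples) {
  as.integer(as.character(samples$class) == "FRI")
}

#' @rdname classLabels
#' @export
setMethod("classLabels", "SpectralDataset", function(object) .labelsFrom(object@samples))

#' @rdname classLabels
#' @export
setMethod("classLabels", "ProteinTable", function(object) .labelsFrom(object@samples))

#' @rdname classLabels
#' @export
setMethod("classLabels", "FeatureMatrix", function(object) .labelsFrom(object@samples))

#' @rdname ProteinTable-class
#' @export
setMethod("ratios", "ProteinTable", function(object) object@ratios)

#' @rdname ProteinTable-class
#' @export
setMethod("proteinIds", "ProteinTable", function(object) object@proteinIds)

#' @rdname FeatureMatrix-class
#' @export
setMethod("features", "FeatureMatrix", function(object) object@features)

#' @rdname FeatureMatrix-class
#' @export
setMethod("featureIds", "FeatureMatrix", function(object) object@featureIds)

#' @rdname FeatureMatrix-class
#' @export
setMethod("retainedIndices", "FeatureMatrix", function(object) object@retainedIndices)

#' @rdname selectedFeatures
#' @export
setMethod("selectedFeatures", "ElasticNetModel", function(object) {
  object@featureIds[object@coefficients != 0]
})

#' @rdname pooledEstimates
#' @export
setMethod("pooledEstimates", "PooledMetrics", function(object) object@estimates)

#' Model coefficients
#'
#' @param object a fitted \linkS4class{ElasticNetModel}.
#' @param ... unused.
#' @return named numeric vector: intercept followed by the per-feature
#'   coefficients on the standardized scale.
#' @export
setMethod("coef", "ElasticNetModel", function(object, ...) {
  c("(Intercept)" = object@intercept,
    stats::setNames(object@coefficients, object@featureIds))
})

setMethod("show", "SpectralDataset", function(object) {
  w <- object@wavenumbers
  cat(sprintf("SpectralDataset: %d replicate spectra of %d samples, %d channels\n",
              nrow(object@absorbance), nrow(object@samples), length(w)))
  cat(sprintf("  wavenumbers: %.1f .. %.1f cm^-1\n", min(w), max(w)))
  cls <- table(as.character(object@samples$class))
  cat(sprintf("  classes: %s\n",
              paste(sprintf("%s=%d", names(cls), cls), collapse = ", ")))
})

setMethod("show", "ProteinTable", function(object) {
  cat(sprintf("ProteinTable: %d samples x %d proteins (abundance ratios)\n",
              nrow(object@ratios), ncol(object@ratios)))
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d samples x %d features\n",
              nrow(object@features), ncol(object@features)))
  if (length(object@retainedIndices))
    cat(sprintf("  retained DCT frequencies: %d (k = %d .. %d)\n",
                length(object@retainedIndices),
                min(object@retainedIndices), max(object@retainedIndices)))
})

setMethod("show", "ElasticNetModel", function(object) {
  cat(sprintf("ElasticNetModel: %d/%d nonzero coefficients (cap %d)\n",
              object@nonzeroCount, length(object@coefficients),
              object@maxNonzero))
  cat(sprintf("  lambda = %.4g, alpha = %.2f\n", object@lambda, object@alpha))
})

setMethod("show", "PooledMetrics", function(object) {
  cat(sprintf("PooledMetrics (%s pooling, %d sessions):\n",
              object@pooling, object@nSessions))
  est <- object@estimates
  for (i in seq_len(nrow(est)))
    cat(sprintf("  %-12s %.3f  CI95 (%.3f, %.3f)\n",
                est$metric[i], est$mean[i], est$ci_lo[i], est$ci_hi[i]))
})

setMethod("show", "CCAResult", function(object) {
  cat(sprintf("CCAResult: %d canonical components\n",
              length(object@correlations)))
  cat("  rho:", paste(sprintf("%.3f", object@correlations), collapse = ", "), "\n")
  if (length(object@pValues))
    cat("  permutation p:",
        paste(sprintf("%.3g", object@pValues), collapse = ", "), "\n")
})
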
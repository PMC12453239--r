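#' Construct a SpectralDataset
#'
#' @param wavenumbers strictly increasing numeric grid (cm^-1).
#' @param absorbance replicates x channels numeric matrix.
#' @param replicateOf sample id per replicate row.
#' @param samples data.frame or DataFrame with \code{sample_id}, \code{class}
#'   (\code{"FRI"}/\code{"control"}) and \code{pair_id}.
#' @param metadata optional provenance list.
#' @return a validated \linkS4class{SpectralDataset}.
#' @export
SpectralDataset <- function(wavenumbers, absorbance, replicateOf, samples,
                            metadata = list()) {
  samples <- S4Vectors::DataFrame(as.data.frame(samples))
  samples$sample_id <- as.character(samples$sample_id)
  samples$class <- as.character(samples$class)
  samples$pair_id <- as.character(samples$pair_id)
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  new("SpectralDataset",
      wavenumbers = as.numeric(wavenumbers), absorbance = absorbance,
      replicateOf = as.character(replicateOf), samples = samples,
      metadata = metadata)
}

#' Construct a ProteinTable
#'
#' @param ratios samples x proteins matrix of positive abundance ratios.
#' @param proteinIds unique protein accessions, one per column.
#' @param samples annotations as for \code{\link{SpectralDataset}}.
#' @param metadata optional provenance list.
#' @return a validated \linkS4class{ProteinTable}.
#' @export
ProteinTable <- function(ratios, proteinIds = colnames(ratios), samples,
                         metadata = list()) {
  samples <- S4Vectors::DataFrame(as.data.frame(samples))
  samples$sample_id <- as.character(samples$sample_id)
  samples$class <- as.character(samples$class)
  samples$pair_id <- as.character(samples$pair_id)
  ratios <- as.matrix(ratios)
  storage.mode(ratios) <- "double"
  if (is.null(proteinIds)) stop("protein ids are required")
  colnames(ratios) <- proteinIds
  rownames(ratios) <- samples$sample_id
  new("ProteinTable", ratios = ratios, proteinIds = as.character(proteinIds),
      samples = samples, metadata = metadata)
}

#' Construct a FeatureMatrix
#'
#' @param features samples x features numeric matrix.
#' @param featureIds unique feature ids, one per column.
#' @param samples annotations as for \code{\link{SpectralDataset}}.
#' @param retainedIndices for spectral features, the original 0-based DCT
#'   frequency of each retained column.
#' @param metadata optional provenance list.
#' @return a validated \linkS4class{FeatureMatrix}.
#' @export
FeatureMatrix <- function(features, featureIds = colnames(features), samples,
                          retainedIndices = integer(), metadata = list()) {
  samples <- S4Vectors::DataFrame(as.data.frame(samples))
  samples$sample_id <- as.character(samples$sample_id)
  samples$class <- as.character(samples$class)
  samples$pair_id <- as.character(samples$pair_id)
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (is.null(featureIds))
    featureIds <- sprintf("f%d", seq_len(ncol(features)))
  colnames(features) <- featureIds
  rownames(features) <- samples$sample_id
  new("FeatureMatrix", features = features,
      featureIds = as.character(featureIds),
      retainedIndices = as.integer(retainedIndices),
      samples = samples, metadata = metadata)
}
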
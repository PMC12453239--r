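#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Replicate-level FTIR spectra with sample annotations
#'
#' Container for dried-plasma-film mid-infrared absorbance spectra. Rows of
#' \code{absorbance} are replicate wells (typically three per plasma sample),
#' columns are spectral channels on a strictly increasing wavenumber grid.
#' Samples are annotated with a class label (\code{"FRI"} or \code{"control"})
#' and a matched-pair identifier; every pair must contain exactly one FRI and
#' one control sample.
#'
#' @slot wavenumbers numeric, strictly increasing wavenumber grid in cm^-1.
#' @slot absorbance numeric matrix, replicates x channels; rownames are
#'   replicate well ids.
#' @slot replicateOf character, one sample id per replicate row.
#' @slot samples \code{DataFrame} with columns \code{sample_id},
#'   \code{class}, \code{pair_id}.
#' @slot metadata list of free-form provenance (e.g. the generating
#'   configuration for synthetic data).
#'
#' @aliases SpectralDataset-class
#' @exportClass SpectralDataset
setClass("SpectralDataset",
  representation(
    wavenumbers = "numeric",
    absorbance  = "matrix",
    replicateOf = "character",
    samples     = "DataFrame",
    metadata    = "list"
  )
)

setValidity("SpectralDataset", function(object) {
  msg <- character()
  w <- object@wavenumbers
  A <- object@absorbance
  if (length(w) != ncol(A))
    msg <- c(msg, "length(wavenumbers) must equal ncol(absorbance)")
  if (length(w) > 1 && any(diff(w) <= 0))
    msg <- c(msg, "wavenumbers must be strictly increasing")
  if (length(object@replicateOf) != nrow(A))
    msg <- c(msg, "replicateOf must have one entry per absorbance row")
  smp <- object@samples
  need <- c("sample_id", "class", "pair_id")
  if (!all(need %in% colnames(smp))) {
    msg <- c(msg, sprintf("samples must have columns %s",
                          paste(need, collapse = ", ")))
  } else {
    ids <- as.character(smp$sample_id)
    if (anyDuplicated(ids))
      msg <- c(msg, "duplicated sample_id in samples")
    if (!all(object@replicateOf %in% ids))
      msg <- c(msg, "replicateOf contains sample ids absent from samples")
    cls <- as.character(smp$class)
    if (!all(cls %in% c("FRI", "control")))
      msg <- c(msg, "class must be 'FRI' or 'control'")
    pr <- split(cls, as.character(smp$pair_id))
    bad <- vapply(pr, function(p)
      !(length(p) == 2L && sum(p == "FRI") == 1L), logical(1))
    if (any(bad))
      msg <- c(msg, "every pair_id must pair exactly one FRI with one control")
  }
  if (length(msg)) msg else TRUE
})

#' Protein abundance-ratio table
#'
#' Sample-level TMT LC-MS/MS protein abundance ratios (strictly positive),
#' one row per plasma sample, one column per protein accession, with the same
#' class/pair annotations as \linkS4class{SpectralDataset}.
#'
#' @slot ratios numeric matrix, samples x proteins, all entries > 0;
#'   rownames are sample ids.
#' @slot proteinIds character, unique protein accessions (column ids).
#' @slot samples \code{DataFrame} with \code{sample_id}, \code{class},
#'   \code{pair_id}.
#' @slot metadata list of provenance.
#'
#' @aliases ProteinTable-class
#' @exportClass ProteinTable
setClass("ProteinTable",
  representation(
    ratios     = "matrix",
    proteinIds = "character",
    samples    = "DataFrame",
    metadata   = "list"
  )
)

setValidity("ProteinTable", function(object) {
  msg <- character()
  R <- object@ratios
  if (length(object@proteinIds) != ncol(R))
    msg <- c(msg, "proteinIds must have one entry per ratio column")
  if (anyDuplicated(object@proteinIds))
    msg <- c(msg, "protein ids must be unique")
  if (any(!is.finite(R)) || any(R <= 0))
    msg <- c(msg, "abundance ratios must be finite and strictly positive")
  smp <- object@samples
  if (!all(c("sample_id", "class", "pair_id") %in% colnames(smp)))
    msg <- c(msg, "samples must have sample_id, class, pair_id")
  else if (nrow(smp) != nrow(R))
    msg <- c(msg, "one ratio row per annotated sample required")
  if (length(msg)) msg else TRUE
})

#' Sample-level feature matrix
#'
#' Features are either retained DCT coefficients of preprocessed spectra or
#' log protein abundance ratios. \code{retainedIndices} records, for spectral
#' features, which DCT frequencies survive the low-frequency /
#' near-zero-variance filter (an index into the original coefficient vector,
#' 0-based frequency k).
#'
#' @slot features numeric matrix, samples x features; rownames are sample ids.
#' @slot featureIds character feature identifiers (e.g. \code{"dct_12"} or
#'   protein accessions).
#' @slot retainedIndices integer, original 0-based DCT frequency per feature
#'   (length 0 for non-spectral features).
#' @slot samples \code{DataFrame} sample annotations (sample_id, class,
#'   pair_id).
#' @slot metadata list of provenance (preprocessing configuration etc.).
#'
#' @aliases FeatureMatrix-class
#' @exportClass FeatureMatrix
setClass("FeatureMatrix",
  representation(
    features        = "matrix",
    featureIds      = "character",
    retainedIndices = "integer",
    samples         = "DataFrame",
    metadata        = "list"
  )
)

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (length(object@featureIds) != ncol(object@features))
    msg <- c(msg, "featureIds must match feature columns")
  if (anyDuplicated(object@featureIds))
    msg <- c(msg, "feature ids must be unique")
  ri <- object@retainedIndices
  if (length(ri) && length(ri) != ncol(object@features))
    msg <- c(msg, "retainedIndices must be empty or one per feature")
  if (nrow(object@samples) != nrow(object@features))
    msg <- c(msg, "one sample annotation row per feature row required")
  if (length(msg)) msg else TRUE
})

#' Fitted sparse elastic-net logistic model
#'
#' Penalized logistic regression with mixed l1/l2 penalty, fitted by cyclic
#' coordinate descent along a decreasing lambda path with a hard cap on the
#' number of nonzero coefficients. Coefficients are on the standardized
#' feature scale; the standardization means/scales are stored so that
#' prediction applies them transparently.
#'
#' @slot intercept numeric(1).
#' @slot coefficients numeric, one per feature (standardized scale).
#' @slot featureIds character, aligned to \code{coefficients}.
#' @slot lambda numeric(1), selected penalty strength.
#' @slot alpha numeric(1), l1/l2 mixing (1 = lasso, 0 = ridge).
#' @slot center,scale numeric, feature standardization parameters.
#' @slot nonzeroCount integer(1), number of nonzero coefficients.
#' @slot maxNonzero integer(1), the cap enforced during path selection.
#' @slot path list with the full lambda path diagnostics (lambda grid,
#'   nonzero counts, in-sample deviances, objective trajectory).
#'
#' @aliases ElasticNetModel-class
#' @exportClass ElasticNetModel
setClass("ElasticNetModel",
  representation(
    intercept    = "numeric",
    coefficients = "numeric",
    featureIds   = "character",
    lambda       = "numeric",
    alpha        = "numeric",
    center       = "numeric",
    scale        = "numeric",
    nonzeroCount = "integer",
    maxNonzero   = "integer",
    path         = "list"
  )
)

setValidity("ElasticNetModel", function(object) {
  msg <- character()
  p <- length(object@coefficients)
  if (length(object@featureIds) != p)
    msg <- c(msg, "featureIds must align with coefficients")
  if (length(object@center) != p || length(object@scale) != p)
    msg <- c(msg, "center/scale must align with coefficients")
  if (object@nonzeroCount != sum(object@coefficients != 0))
    msg <- c(msg, "nonzeroCount must equal the number of nonzero coefficients")
  if (object@nonzeroCount > object@maxNonzero)
    msg <- c(msg, "nonzero coefficient count exceeds maxNonzero cap")
  if (object@alpha < 0 || object@alpha > 1)
    msg <- c(msg, "alpha must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Fixed-effect pooled classifier performance
#'
#' Inverse-variance (fixed-effect) pooling of per-session bootstrap estimates
#' of AUROC, sensitivity and specificity, with 95% confidence intervals.
#'
#' @slot estimates data.frame with one row per metric: pooled mean,
#'   between-session SD, CI95 lower/upper.
#' @slot nSessions integer(1).
#' @slot pooling character(1), \code{"ivw"} (inverse-variance weighting) or
#'   \code{"mean"} (unweighted).
#'
#' @aliases PooledMetrics-class
#' @exportClass PooledMetrics
setClass("PooledMetrics",
  representation(
    estimates = "data.frame",
    nSessions = "integer",
    pooling   = "character"
  )
)

setValidity("PooledMetrics", function(object) {
  msg <- character()
  est <- object@estimates
  need <- c("metric", "mean", "sd", "ci_lo", "ci_hi")
  if (!all(need %in% colnames(est)))
    msg <- c(msg, sprintf("estimates must have columns %s",
                          paste(need, collapse = ", ")))
  else if (any(est$ci_lo > est$mean + 1e-12 | est$ci_hi < est$mean - 1e-12))
    msg <- c(msg, "CI must bracket the pooled mean")
  if (length(msg)) msg else TRUE
})

#' Canonical correlation analysis result
#'
#' Canonical vectors and correlations between two sample-matched data
#' matrices (here: discriminatory raw-wavenumber FTIR features and
#' discriminatory MS proteins), with optional permutation p-values.
#'
#' @slot xVectors,yVectors numeric matrices of canonical vectors (columns,
#'   on the standardized-variable scale).
#' @slot correlations numeric, non-increasing canonical correlations in
#'   [0, 1].
#' @slot pValues numeric, permutation p-value per component (may be empty
#'   until \code{\link{ccaPermutationTest}} is run).
#' @slot ridge numeric(1), ridge stabilization applied to the within-set
#'   covariances (0 when none was needed).
#'
#' @aliases CCAResult-class
#' @exportClass CCAResult
setClass("CCAResult",
  representation(
    xVectors     = "matrix",
    yVectors     = "matrix",
    correlations = "numeric",
    pValues      = "numeric",
    ridge        = "numeric"
  )
)

setValidity("CCAResult", function(object) {
  msg <- character()
  r <- object@correlations
  if (length(r)) {
    if (any(r < -1e-8 | r > 1 + 1e-8))
      msg <- c(msg, "canonical correlations must lie in [0, 1]")
    if (length(r) > 1 && any(diff(r) > 1e-8))
      msg <- c(msg, "canonical correlations must be non-increasing")
  }
  p <- object@pValues
  if (length(p) && any(p <= 0 | p > 1))
    msg <- c(msg, "permutation p-values must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})
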
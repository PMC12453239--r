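# Spectral preprocessing chain, applied per replicate spectrum in this
# order: area normalization -> additive log-ratio against the thiocyanate
# internal-standard band -> Savitzky-Golay filtering -> removal of the
# internal-standard band; replicates are then averaged to sample level,
# each sample spectrum is compressed with the orthonormal DCT-II, and
# uninformative frequencies are filtered out.

#' Normalize a spectrum to unit area under the curve
#'
#' @param row absorbance vector over \code{wavenumbers}.
#' @param wavenumbers strictly increasing grid (cm^-1).
#' @return the row scaled so its trapezoidal integral over the grid is 1.
#' @export
areaNormalize <- function(row, wavenumbers) {
  stopifnot(length(row) == length(wavenumbers))
  area <- .trapz(wavenumbers, row)
  if (!is.finite(area) || area <= 0)
    stop("value error: non-positive area under the curve")
  row / area
}

.trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Additive log-ratio transform against the internal-standard band
#'
#' Each channel is expressed as the natural log of its absorbance relative
#' to the mean absorbance within the KSCN internal-standard band, making
#' spectra invariant to global intensity scale (film thickness, optical
#' path). Values are clipped at a small positive epsilon before the log,
#' since dried-film baselines can dip at or below zero.
#'
#' @param row (area-normalized) absorbance vector.
#' @param wavenumbers grid (cm^-1).
#' @param band numeric length-2, the internal-standard band \code{[lo, hi]}.
#' @param epsilonRel clip floor relative to \code{max(row)}.
#' @return \code{log(pmax(row, eps)) - log(r)} with \code{r} the clipped
#'   band mean.
#' @export
alrKscn <- function(row, wavenumbers, band = c(2000, 2150),
                    epsilonRel = 1e-8) {
  stopifnot(length(row) == length(wavenumbers), length(band) == 2)
  mx <- max(row)
  if (!is.finite(mx) || mx <= 0)
    stop("value error: spectrum has no positive absorbance")
  eps <- epsilonRel * mx
  clipped <- pmax(row, eps)
  inBand <- wavenumbers >= band[1] & wavenumbers <= band[2]
  if (!any(inBand))
    stop("value error: internal-standard band contains no channels")
  r <- mean(clipped[inBand])
  if (r <= 0) stop("value error: non-positive internal-standard band mean")
  log(clipped) - log(r)
}

#' Savitzky-Golay filtering
#'
#' Local least-squares polynomial smoothing (optionally a derivative
#' filter), used to suppress baseline drift and channel noise. Edge points
#' are handled by polynomial fits of the terminal windows.
#'
#' @param row numeric vector, length >= \code{window}.
#' @param window odd window length in channels.
#' @param polyorder polynomial order, < \code{window}.
#' @param deriv derivative order (0 = smoothing).
#' @return the filtered vector, same length.
#' @export
savitzkyGolay <- function(row, window = 11L, polyorder = 3L, deriv = 0L) {
  if (window %% 2 == 0) stop("config error: window must be odd")
  if (window <= polyorder)
    stop("config error: window must exceed polyorder")
  if (length(row) < window)
    stop("value error: spectrum shorter than the filter window")
  as.numeric(signal::sgolayfilt(row, p = polyorder, n = window, m = deriv))
}

#' Delete a wavenumber band from a spectrum
#'
#' @param x numeric vector, or matrix with one channel per column.
#' @param wavenumbers grid aligned to the channels of \code{x}.
#' @param band \code{[lo, hi]} in cm^-1; channels inside (inclusive) are
#'   removed, order of the rest preserved.
#' @return list with \code{values} (same shape as \code{x}, fewer channels)
#'   and \code{wavenumbers} (still strictly increasing).
#' @export
removeBand <- function(x, wavenumbers, band) {
  stopifnot(length(band) == 2)
  keep <- wavenumbers < band[1] | wavenumbers > band[2]
  if (!any(keep)) stop("value error: band removal would delete every channel")
  if (is.matrix(x)) {
    stopifnot(ncol(x) == length(wavenumbers))
    list(values = x[, keep, drop = FALSE], wavenumbers = wavenumbers[keep])
  } else {
    stopifnot(length(x) == length(wavenumbers))
    list(values = x[keep], wavenumbers = wavenumbers[keep])
  }
}

# Orthonormal DCT-II of each matrix row, computed through the FFT
# (even/odd reordering with a quarter-sample phase shift).
.dctRows <- function(M) {
  N <- ncol(M)
  if (N < 1) stop("value error: empty spectrum")
  if (N == 1) return(M)  # X0 = x0 for the orthonormal convention
  idx <- c(seq(1, N, by = 2), rev(seq(2, N, by = 2)))
  V <- stats::mvfft(t(M[, idx, drop = FALSE]))
  k <- 0:(N - 1)
  phase <- exp(-1i * pi * k / (2 * N))
  X <- Re(V * phase)                       # N x nrow, unnormalized DCT-II
  scale <- rep(sqrt(2 / N), N)
  scale[1] <- sqrt(1 / N)                  # C0 = 1/sqrt(2) absorbed here
  t(X * scale)
}

#' Orthonormal discrete cosine transform (DCT-II)
#'
#' \deqn{X_k = \sqrt{2/N}\, C_k \sum_{n=0}^{N-1} x_n
#'   \cos\!\left(\frac{\pi}{N}\left(n + \tfrac12\right)k\right),\quad
#'   C_0 = 1/\sqrt2,\; C_k = 1 \;(k>0),}
#' the energy-preserving convention: \code{sum(X^2) == sum(x^2)} and the
#' transform is invertible by its transpose.
#'
#' @param x numeric vector (a preprocessed sample spectrum).
#' @return numeric vector of DCT coefficients, frequencies k = 0..N-1.
#' @seealso \code{\link{inverseDct}}
#' @export
dctTransform <- function(x) {
  if (!length(x)) stop("value error: empty spectrum")
  drop(.dctRows(matrix(x, nrow = 1)))
}

#' Inverse of \code{\link{dctTransform}}
#'
#' @param X orthonormal DCT-II coefficients.
#' @return the reconstructed signal.
#' @export
inverseDct <- function(X) {
  N <- length(X)
  if (!N) stop("value error: empty coefficient vector")
  n <- 0:(N - 1)
  basis <- vapply(0:(N - 1), function(k) {
    ck <- if (k == 0) 1 / sqrt(2) else 1
    sqrt(2 / N) * ck * cos(pi / N * (n + 0.5) * k)
  }, numeric(N))
  drop(basis %*% X)
}

#' Drop uninformative DCT frequencies
#'
#' Removes the listed leading frequencies (by default k = 0, the spectrum
#' mean, which after the log-ratio normalization carries near-zero
#' between-sample variance) plus any coefficient whose across-sample
#' variance falls below \code{nearZeroVarRel} times the largest
#' across-sample variance.
#'
#' @param dctMatrix samples x frequencies coefficient matrix (frequency k
#'   in column k+1).
#' @param dropK integer frequencies (0-based) to drop unconditionally.
#' @param nearZeroVarRel relative variance floor.
#' @return list with \code{coefficients} (samples x retained) and
#'   \code{retained} (0-based frequencies kept, increasing).
#' @export
frequencyFilter <- function(dctMatrix, dropK = 0L, nearZeroVarRel = 1e-8) {
  if (nrow(dctMatrix) < 2)
    stop("value error: at least two samples required")
  N <- ncol(dctMatrix)
  k <- 0:(N - 1)
  keep <- !(k %in% dropK)
  v <- apply(dctMatrix, 2, stats::var)
  if (max(v) <= 0)
    stop("value error: frequency filtering removed every coefficient ",
         "(no across-sample variance)")
  keep <- keep & (v >= nearZeroVarRel * max(v)) & (v > 0)
  if (!any(keep))
    stop("value error: frequency filtering removed every coefficient")
  list(coefficients = dctMatrix[, keep, drop = FALSE],
       retained = k[keep])
}

#' Average replicate spectra to sample level
#'
#' @param dataset a \linkS4class{SpectralDataset} (or a replicate matrix
#'   plus \code{replicateOf}/\code{sampleIds}).
#' @param values optional matrix overriding the dataset's absorbance (used
#'   by the pipeline after per-replicate stages).
#' @return samples x channels matrix of arithmetic replicate means, rows in
#'   metadata sample order.
#' @export
averageReplicates <- function(dataset, values = NULL) {
  A <- if (is.null(values)) absorbance(dataset) else values
  repOf <- replicateOf(dataset)
  ids <- as.character(sampleInfo(dataset)$sample_id)
  out <- matrix(0, length(ids), ncol(A),
                dimnames = list(ids, colnames(A)))
  for (s in ids) {
    rows <- which(repOf == s)
    if (!length(rows))
      stop("metadata error: sample without replicates: ", s)
    out[s, ] <- colMeans(A[rows, , drop = FALSE])
  }
  out
}

#' Full spectral preprocessing pipeline
#'
#' Applies, per replicate spectrum: \code{\link{areaNormalize}},
#' \code{\link{alrKscn}}, \code{\link{savitzkyGolay}},
#' \code{\link{removeBand}} (internal-standard band); then
#' \code{\link{averageReplicates}}; then \code{\link{dctTransform}} per
#' sample; then \code{\link{frequencyFilter}}. Deterministic; the retained
#' DCT frequencies and the configuration are recorded on the result.
#'
#' @param dataset a \linkS4class{SpectralDataset}.
#' @param config a \code{\link{runConfig}} (its \code{$preprocess} section
#'   is used) or the section itself.
#' @return a \linkS4class{FeatureMatrix} of retained DCT coefficients with
#'   feature ids \code{"dct_<k>"}.
#' @export
preprocessSpectra <- function(dataset, config = runConfig()) {
  p <- if (!is.null(config$preprocess)) config$preprocess else config
  w <- wavenumbers(dataset)
  A <- absorbance(dataset)
  proc <- t(apply(A, 1, function(row) {
    row <- areaNormalize(row, w)
    row <- alrKscn(row, w, p$kscn_band, p$positivity_epsilon_rel)
    savitzkyGolay(row, p$sg_window, p$sg_polyorder, p$sg_deriv)
  }))
  cut <- removeBand(proc, w, p$kscn_band)
  sampleLevel <- averageReplicates(dataset, values = cut$values)
  coefs <- .dctRows(sampleLevel)
  filt <- frequencyFilter(coefs, dropK = p$dct_drop_k,
                          nearZeroVarRel = p$near_zero_var_rel)
  FeatureMatrix(filt$coefficients,
                featureIds = sprintf("dct_%d", filt$retained),
                samples = sampleInfo(dataset),
                retainedIndices = filt$retained,
                metadata = list(preprocess = p,
                                wavenumbers_after_cut = cut$wavenumbers))
}
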
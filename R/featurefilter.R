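# Univariate feature screening: each feature (DCT coefficient or log
# protein ratio) is tested one by one with a pooled-variance two-sample
# t-test and Cohen's d; features with |d| above the threshold are retained.
# No multiplicity correction is applied at this stage.

#' Cohen's d (pooled-SD standardized mean difference)
#'
#' \code{d = (mean(A) - mean(B)) / s_pooled} with
#' \code{s_pooled^2 = ((nA-1) sA^2 + (nB-1) sB^2) / (nA + nB - 2)},
#' sample variances with denominator n-1.
#'
#' @param groupA,groupB numeric vectors, each of length >= 2.
#' @return the signed effect size d.
#' @export
cohensD <- function(groupA, groupB) {
  nA <- length(groupA); nB <- length(groupB)
  if (nA < 2 || nB < 2) stop("value error: each group needs >= 2 values")
  sp2 <- ((nA - 1) * stats::var(groupA) + (nB - 1) * stats::var(groupB)) /
    (nA + nB - 2)
  if (sp2 <= 0) stop("value error: degenerate feature (zero pooled SD)")
  (mean(groupA) - mean(groupB)) / sqrt(sp2)
}

#' Pooled-variance two-sample Student t-test
#'
#' @param groupA,groupB numeric vectors, each of length >= 2.
#' @return list with \code{statistic} (t), \code{p} (two-sided) and
#'   \code{df}.
#' @export
twoSampleTTest <- function(groupA, groupB) {
  nA <- length(groupA); nB <- length(groupB)
  if (nA < 2 || nB < 2) stop("value error: each group needs >= 2 values")
  sp2 <- ((nA - 1) * stats::var(groupA) + (nB - 1) * stats::var(groupB)) /
    (nA + nB - 2)
  if (sp2 <= 0) stop("value error: degenerate feature (zero pooled SD)")
  df <- nA + nB - 2
  t <- (mean(groupA) - mean(groupB)) / sqrt(sp2 * (1 / nA + 1 / nB))
  list(statistic = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

# Vectorized per-column t/d over a matrix; returns NA d for degenerate
# (zero pooled variance) columns rather than erroring, so callers can
# drop them with a warning.
.columnEffects <- function(X, labels) {
  a <- labels == 1L; b <- labels == 0L
  nA <- sum(a); nB <- sum(b)
  mA <- colMeans(X[a, , drop = FALSE]); mB <- colMeans(X[b, , drop = FALSE])
  vA <- .colVars(X[a, , drop = FALSE], mA)
  vB <- .colVars(X[b, , drop = FALSE], mB)
  sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  ok <- sp2 > 0
  d <- t <- p <- rep(NA_real_, ncol(X))
  d[ok] <- (mA[ok] - mB[ok]) / sqrt(sp2[ok])
  t[ok] <- (mA[ok] - mB[ok]) / sqrt(sp2[ok] * (1 / nA + 1 / nB))
  p[ok] <- 2 * stats::pt(-abs(t[ok]), nA + nB - 2)
  list(t = t, p = p, d = d)
}

.colVars <- function(X, mu = colMeans(X)) {
  n <- nrow(X)
  (colSums(X^2) - n * mu^2) / (n - 1)
}

#' Screen features by effect size
#'
#' Retains the columns whose |Cohen's d| between FRI and control exceeds the
#' threshold (two-sided: separations in either direction count). Degenerate
#' zero-variance columns are dropped with a warning.
#'
#' @param x a \linkS4class{FeatureMatrix} or plain samples x features
#'   matrix.
#' @param labels binary labels (1 = FRI); taken from the annotations when
#'   \code{x} is a \code{FeatureMatrix}.
#' @param threshold retention threshold on |d| (default 0.5).
#' @return list with \code{filtered} (same type as \code{x}, retained
#'   columns only) and \code{result}: per-feature \code{t}, \code{p},
#'   \code{d}, logical \code{retained}, and the threshold used.
#' @export
filterFeatures <- function(x, labels = NULL, threshold = 0.5) {
  isFM <- is(x, "FeatureMatrix")
  X <- if (isFM) features(x) else as.matrix(x)
  if (is.null(labels)) {
    if (!isFM) stop("labels required for a plain matrix")
    labels <- classLabels(x)
  }
  if (length(unique(labels)) < 2)
    stop("value error: both classes must be present")
  eff <- .columnEffects(X, labels)
  degen <- is.na(eff$d)
  if (any(degen))
    warning(sum(degen), " degenerate zero-variance feature(s) dropped")
  retained <- !degen & abs(eff$d) > threshold
  res <- data.frame(feature = colnames(X) %||% sprintf("f%d", seq_len(ncol(X))),
                    t = eff$t, p = eff$p, d = eff$d, retained = retained)
  if (!any(retained)) {
    stop("value error: no feature exceeds |d| > ", threshold,
         " (max |d| = ", signif(max(abs(eff$d), na.rm = TRUE), 3), ")")
  }
  filtered <- if (isFM) {
    ri <- retainedIndices(x)
    FeatureMatrix(X[, retained, drop = FALSE],
                  featureIds = featureIds(x)[retained],
                  samples = sampleInfo(x),
                  retainedIndices = if (length(ri)) ri[retained] else integer(),
                  metadata = x@metadata)
  } else X[, retained, drop = FALSE]
  list(filtered = filtered,
       result = structure(res, threshold = threshold))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
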
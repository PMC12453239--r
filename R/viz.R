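# Discriminant visualization: the selected features are compressed with a
# column-centered SVD (PCA scores), a Fisher linear discriminant is trained
# in the component space, and each class cloud is summarized by a
# 95-percentile confidence ellipse from a multivariate-t radial quantile.

#' SVD/PCA compression of a feature matrix
#'
#' Column-centers \code{X} and truncates its SVD.
#'
#' @param X samples x features numeric matrix.
#' @param nComponents number of retained components (default 15).
#' @return list with \code{scores} (samples x nComponents = U * S),
#'   \code{explained} (variance fractions, non-increasing),
#'   \code{rotation} (loadings) and \code{center}.
#' @export
svdCompress <- function(X, nComponents = 15L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (nComponents > min(n - 1, ncol(X)))
    stop("value error: nComponents exceeds min(samples - 1, features)")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc, nu = nComponents, nv = nComponents)
  d2 <- sv$d^2
  list(scores = sv$u %*% diag(sv$d[seq_len(nComponents)], nComponents),
       explained = (d2 / sum(d2))[seq_len(nComponents)],
       rotation = sv$v, center = ctr)
}

# Symmetric inverse square root via eigendecomposition, with a recorded
# ridge when near-singular.
.invSqrt <- function(S, ridgeRel = 1e-8) {
  e <- eigen(S, symmetric = TRUE)
  eps <- 0
  if (min(e$values) < ridgeRel * max(e$values)) {
    eps <- ridgeRel * max(e$values, 1e-300)
    e <- eigen(S + diag(eps, nrow(S)), symmetric = TRUE)
  }
  list(mat = e$vectors %*% (t(e$vectors) / sqrt(e$values)), ridge = eps)
}

#' Two-dimensional linear-discriminant coordinates
#'
#' A two-class problem has a single Fisher discriminant; for a planar view
#' the first coordinate holds the discriminant scores (direction maximizing
#' the between- to within-class variance ratio, scaled to unit within-class
#' SD, which makes it exactly invariant to any invertible linear feature
#' rescaling). The second coordinate is the leading principal direction of
#' the within-class residuals after removing their within-class regression
#' on coordinate 1, so the two axes are within-class uncorrelated. (A
#' whitened "orthogonal residual PC" would be degenerate: sphering makes
#' the within-class residuals exactly isotropic.)
#'
#' @param scores samples x components matrix (e.g. from
#'   \code{\link{svdCompress}}).
#' @param labels binary labels (1 = FRI).
#' @return list with \code{coordinates} (samples x 2, each unit
#'   within-class SD), \code{ridge} (the within-class scatter
#'   regularization used, 0 if none).
#' @export
ldaCoordinates <- function(scores, labels) {
  X <- as.matrix(scores)
  y <- as.integer(labels)
  if (length(unique(y)) != 2) stop("value error: two classes required")
  if (min(table(y)) < 3) stop("value error: >= 3 samples per class required")
  mu1 <- colMeans(X[y == 1, , drop = FALSE])
  mu0 <- colMeans(X[y == 0, , drop = FALSE])
  R <- X
  R[y == 1, ] <- sweep(X[y == 1, , drop = FALSE], 2, mu1)
  R[y == 0, ] <- sweep(X[y == 0, , drop = FALSE], 2, mu0)
  W <- crossprod(R) / (nrow(X) - 2)
  eps <- 0
  e <- eigen(W, symmetric = TRUE, only.values = TRUE)$values
  if (min(e) < 1e-8 * max(e)) {
    eps <- 1e-8 * max(e, 1e-300)
    W <- W + diag(eps, ncol(W))
  }
  w1 <- drop(solve(W, mu1 - mu0))
  c1 <- drop(X %*% w1)
  s1 <- drop(R %*% w1)                     # within-class part of coord 1
  sd1 <- sqrt(sum(s1^2) / (nrow(X) - 2))
  # within-class residuals decorrelated from coordinate 1
  Rp <- R - outer(s1, drop(crossprod(R, s1)) / sum(s1^2))
  v2 <- svd(Rp, nu = 0, nv = 1)$v[, 1]
  # residualize the coordinate-2 functional against coordinate 1 so the
  # two axes are within-class uncorrelated
  r2 <- drop(R %*% v2)
  gamma <- sum(r2 * s1) / sum(s1^2)
  c2 <- drop(X %*% v2) - gamma * c1
  s2 <- r2 - gamma * s1
  sd2 <- sqrt(sum(s2^2) / (nrow(X) - 2))
  coords <- cbind(ld1 = c1 / sd1, ld2 = c2 / max(sd2, 1e-300))
  list(coordinates = coords, ridge = eps)
}

#' Confidence ellipse of a planar class cloud
#'
#' Center = sample mean; shape = sample covariance scaled by the radial
#' quantile of a fitted bivariate t distribution, taken as
#' \code{2 * qf(level, 2, n - 1)} so the region approaches the chi-square
#' ellipse for large n and widens for small classes.
#'
#' @param points n x 2 matrix (n >= 3).
#' @param level coverage level in [0, 1) (default 0.95; 0 gives a
#'   degenerate point).
#' @return list with \code{center}, \code{shape} (covariance),
#'   \code{radius2} (squared Mahalanobis radius), \code{level}, \code{n}.
#' @export
confidenceEllipse <- function(points, level = 0.95) {
  P <- as.matrix(points)
  if (ncol(P) != 2 || nrow(P) < 3)
    stop("value error: >= 3 two-dimensional points required")
  S <- stats::cov(P)
  if (det(S) <= 0) stop("value error: degenerate covariance")
  n <- nrow(P)
  list(center = colMeans(P), shape = S,
       radius2 = 2 * stats::qf(level, 2, n - 1), level = level, n = n)
}

#' Boundary polygon of a confidence ellipse
#'
#' @param ellipse result of \code{\link{confidenceEllipse}}.
#' @param nPoints polygon resolution.
#' @return nPoints x 2 matrix tracing the ellipse boundary.
#' @export
ellipsePoints <- function(ellipse, nPoints = 100L) {
  theta <- seq(0, 2 * pi, length.out = nPoints)
  circ <- rbind(cos(theta), sin(theta)) * sqrt(ellipse$radius2)
  t(ellipse$center + t(chol(ellipse$shape)) %*% circ)
}

#' Discriminant projection of selected features
#'
#' Composes the visualization stages: restrict to the model-selected
#' features, compress with \code{\link{svdCompress}}, project with
#' \code{\link{ldaCoordinates}} and fit per-class confidence ellipses.
#'
#' @param fm a \linkS4class{FeatureMatrix}.
#' @param selected character vector of feature ids (e.g. from
#'   \code{\link{rankFeatures}} or \code{\link{selectedFeatures}});
#'   \code{NULL} uses all columns.
#' @param nComponents principal components retained (default 15, capped at
#'   what the data supports).
#' @param level ellipse coverage level.
#' @return list of class \code{"projectionResult"}: \code{scores},
#'   \code{explained}, \code{coordinates}, \code{ellipses} (per class),
#'   \code{labels}.
#' @export
discriminantProjection <- function(fm, selected = NULL, nComponents = 15L,
                                   level = 0.95) {
  X <- features(fm)
  if (!is.null(selected)) {
    keep <- intersect(selected, colnames(X))
    if (length(keep) < 2) stop("value error: need >= 2 selected features")
    X <- X[, keep, drop = FALSE]
  }
  y <- classLabels(fm)
  nc <- min(nComponents, nrow(X) - 1L, ncol(X))
  comp <- svdCompress(X, nc)
  lda <- ldaCoordinates(comp$scores, y)
  co <- lda$coordinates
  ell <- list(FRI = confidenceEllipse(co[y == 1, , drop = FALSE], level),
              control = confidenceEllipse(co[y == 0, , drop = FALSE], level))
  structure(list(scores = comp$scores, explained = comp$explained,
                 coordinates = co, ellipses = ell, labels = y,
                 ridge = lda$ridge),
            class = "projectionResult")
}

#' Plot a discriminant projection
#'
#' @param x a \code{projectionResult}.
#' @param ... passed to \code{plot}.
#' @return \code{x}, invisibly.
#' @export
plotProjection <- function(x, ...) {
  co <- x$coordinates
  cols <- ifelse(x$labels == 1, "#D55E00", "#0072B2")
  plot(co, col = cols, pch = 19, xlab = "LD 1",
       ylab = "within-class residual PC 1", ...)
  for (i in seq_along(x$ellipses)) {
    bp <- ellipsePoints(x$ellipses[[i]])
    graphics::lines(bp, col = c("#D55E00", "#0072B2")[i], lty = 2)
  }
  graphics::legend("topright", legend = c("FRI", "control"),
                   col = c("#D55E00", "#0072B2"), pch = 19, bty = "n")
  invisible(x)
}
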
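# Cross-modal association between the FTIR and MS readouts: canonical
# correlation analysis with permutation significance, and a small
# cross-modal autoencoder whose 2-node bottleneck must carry any structure
# shared between the modalities.

#' Canonical correlation analysis
#'
#' Finds linear projections a, b of the two (column-standardized) matrices
#' maximizing \code{cor(Xa, Yb)}: the canonical correlations are the
#' singular values of \code{Sxx^(-1/2) Sxy Syy^(-1/2)}; the vectors are
#' back-transformed through the inverse square roots. Near-singular
#' within-set covariances are ridge-stabilized, with the ridge recorded.
#'
#' @param X,Y samples x p and samples x q matrices, same row order
#'   (p, q < samples unless a ridge is supplied).
#' @param k number of components (default \code{min(p, q)}).
#' @param ridgeRel relative ridge threshold/size for near-singular
#'   covariances.
#' @return a \linkS4class{CCAResult} (permutation p-values empty; see
#'   \code{\link{ccaPermutationTest}}).
#' @export
ccaFit <- function(X, Y, k = NULL, ridgeRel = 1e-8) {
  X <- scale(as.matrix(X)); Y <- scale(as.matrix(Y))
  n <- nrow(X)
  if (nrow(Y) != n) stop("value error: X and Y must share samples")
  p <- ncol(X); q <- ncol(Y)
  if (is.null(k)) k <- min(p, q)
  if ((p >= n || q >= n) && ridgeRel <= 0)
    stop("conditioning error: p or q >= samples requires regularization")
  Sxx <- stats::cov(X); Syy <- stats::cov(Y)
  Sxy <- stats::cov(X, Y)
  ix <- .invSqrt(Sxx, ridgeRel); iy <- .invSqrt(Syy, ridgeRel)
  M <- ix$mat %*% Sxy %*% iy$mat
  sv <- svd(M, nu = k, nv = k)
  rho <- pmin(pmax(sv$d[seq_len(k)], 0), 1)
  new("CCAResult",
      xVectors = ix$mat %*% sv$u, yVectors = iy$mat %*% sv$v,
      correlations = rho, pValues = numeric(0),
      ridge = max(ix$ridge, iy$ridge))
}

#' Permutation significance of canonical correlations
#'
#' Re-runs \code{\link{ccaFit}} with the rows of \code{Y} permuted
#' \code{nPerm} times; per component,
#' \code{p = (1 + #{rho_perm >= rho_obs}) / (1 + nPerm)} (never below
#' \code{1/(1+nPerm)}).
#'
#' @param X,Y as in \code{\link{ccaFit}}.
#' @param k components.
#' @param nPerm number of permutations (default 1000).
#' @param seed RNG seed.
#' @param ridgeRel passed to \code{\link{ccaFit}}.
#' @return the observed \linkS4class{CCAResult} with \code{pValues} filled.
#' @export
ccaPermutationTest <- function(X, Y, k = NULL, nPerm = 1000L, seed = 1L,
                               ridgeRel = 1e-8) {
  if (nPerm < 1) stop("value error: nPerm must be >= 1")
  obs <- ccaFit(X, Y, k, ridgeRel)
  k <- length(obs@correlations)
  exceed <- integer(k)
  .withSeed(seed, {
    n <- nrow(as.matrix(Y))
    for (b in seq_len(nPerm)) {
      perm <- sample.int(n)
      rp <- ccaFit(X, as.matrix(Y)[perm, , drop = FALSE], k, ridgeRel)@correlations
      exceed <- exceed + as.integer(rp >= obs@correlations - 1e-12)
    }
  })
  obs@pValues <- (1 + exceed) / (1 + nPerm)
  validObject(obs)
  obs
}

#' Pre-select discriminatory features for cross-modal analysis
#'
#' Picks the top-k features per modality by |Cohen's d| between classes:
#' raw replicate-averaged FTIR wavenumber channels (no DCT) and protein
#' log ratios, matching the association analysis inputs.
#'
#' @param spectra a \linkS4class{SpectralDataset}.
#' @param proteins a \linkS4class{ProteinTable}.
#' @param topK features kept per modality (default 8, keeping the CCA
#'   well-posed for 26 samples).
#' @return list with matrices \code{X} (FTIR) and \code{Y} (MS), plus the
#'   chosen column ids.
#' @export
crossmodalInputs <- function(spectra, proteins, topK = 8L) {
  stopifnot(identical(as.character(sampleInfo(spectra)$sample_id),
                      as.character(sampleInfo(proteins)$sample_id)))
  Xfull <- averageReplicates(spectra)
  colnames(Xfull) <- sprintf("wn_%g", wavenumbers(spectra))
  y <- classLabels(spectra)
  dx <- abs(.columnEffects(Xfull, y)$d)
  keepX <- order(-dx)[seq_len(min(topK, ncol(Xfull)))]
  Yfull <- log(ratios(proteins))
  dy <- abs(.columnEffects(Yfull, y)$d)
  keepY <- order(-dy)[seq_len(min(topK, ncol(Yfull)))]
  list(X = Xfull[, sort(keepX), drop = FALSE],
       Y = Yfull[, sort(keepY), drop = FALSE],
       x_ids = colnames(Xfull)[sort(keepX)],
       y_ids = colnames(Yfull)[sort(keepY)])
}

# --- minimal dense MLP machinery (tanh hidden layers, linear output) ----

.mlpInit <- function(sizes) {
  lapply(seq_len(length(sizes) - 1), function(l) {
    fanIn <- sizes[l]; fanOut <- sizes[l + 1]
    list(W = matrix(stats::rnorm(fanIn * fanOut, 0, sqrt(1 / fanIn)),
                    fanIn, fanOut),
         b = rep(0, fanOut))
  })
}

.mlpForward <- function(layers, X) {
  L <- length(layers)
  acts <- vector("list", L + 1)
  acts[[1]] <- X
  for (l in seq_len(L)) {
    Z <- sweep(acts[[l]] %*% layers[[l]]$W, 2, layers[[l]]$b, `+`)
    acts[[l + 1]] <- if (l < L) tanh(Z) else Z
  }
  acts
}

# gradOut: dLoss/dOutput. Returns per-layer grads (same shapes as layers).
.mlpBackward <- function(layers, acts, gradOut) {
  L <- length(layers)
  grads <- vector("list", L)
  delta <- gradOut
  for (l in rev(seq_len(L))) {
    if (l < L) delta <- delta * (1 - acts[[l + 1]]^2)  # tanh'
    grads[[l]] <- list(W = crossprod(acts[[l]], delta),
                       b = colSums(delta))
    if (l > 1) delta <- delta %*% t(layers[[l]]$W)
  }
  grads
}

#' Train the cross-modal autoencoder
#'
#' Each modality passes through three tanh dense layers into a 2-node
#' bottleneck; the mirrored decoder reconstructs the opposite modality.
#' Both paths (X to Y-hat, Y to X-hat) are trained jointly by full-batch
#' Adam on the summed mean-squared reconstruction error of the
#' column-standardized inputs.
#'
#' @param X,Y samples x p / samples x q matrices (standardized internally).
#' @param widths encoder hidden widths before the 2-node bottleneck.
#' @param epochs training epochs.
#' @param learningRate Adam step size.
#' @param seed RNG seed for the (deterministic) initialization.
#' @return list of class \code{"autoencoderResult"}: \code{loss}
#'   (per-epoch trajectory), \code{embedding} (samples x 2 bottleneck
#'   activations of the X path), \code{embedding_y}, final per-path losses
#'   and the architecture.
#' @export
crossmodalAutoencoder <- function(X, Y, widths = c(64L, 16L, 4L),
                                  epochs = 2000L, learningRate = 0.01,
                                  seed = 1L) {
  X <- scale(as.matrix(X)); Y <- scale(as.matrix(Y))
  n <- nrow(X)
  stopifnot(nrow(Y) == n)
  sizesX <- c(ncol(X), widths, 2L, rev(widths), ncol(Y))
  sizesY <- c(ncol(Y), widths, 2L, rev(widths), ncol(X))
  bnAct <- length(widths) + 2L   # activation-list index of the bottleneck
  .withSeed(seed, {
    netX <- .mlpInit(sizesX)
    netY <- .mlpInit(sizesY)
    state <- list()
    adam <- function(key, grad, theta, t) {
      st <- state[[key]] %||% list(m = 0 * grad, v = 0 * grad)
      st$m <- 0.9 * st$m + 0.1 * grad
      st$v <- 0.999 * st$v + 0.001 * grad^2
      state[[key]] <<- st
      mh <- st$m / (1 - 0.9^t); vh <- st$v / (1 - 0.999^t)
      theta - learningRate * mh / (sqrt(vh) + 1e-8)
    }
    loss <- numeric(epochs)
    for (ep in seq_len(max(epochs, 0L))) {
      aX <- .mlpForward(netX, X)
      aY <- .mlpForward(netY, Y)
      errX <- aX[[length(aX)]] - Y          # X path reconstructs Y
      errY <- aY[[length(aY)]] - X
      loss[ep] <- mean(errX^2) + mean(errY^2)
      if (!is.finite(loss[ep]))
        stop("training error: loss diverged; reduce the learning rate")
      # back off the step size whenever the full-batch loss rises, so the
      # trajectory settles monotonically
      if (ep > 1 && loss[ep] > loss[ep - 1]) learningRate <- 0.8 * learningRate
      gX <- .mlpBackward(netX, aX, 2 * errX / length(errX))
      gY <- .mlpBackward(netY, aY, 2 * errY / length(errY))
      for (l in seq_along(netX)) {
        netX[[l]]$W <- adam(paste0("xW", l), gX[[l]]$W, netX[[l]]$W, ep)
        netX[[l]]$b <- adam(paste0("xb", l), gX[[l]]$b, netX[[l]]$b, ep)
      }
      for (l in seq_along(netY)) {
        netY[[l]]$W <- adam(paste0("yW", l), gY[[l]]$W, netY[[l]]$W, ep)
        netY[[l]]$b <- adam(paste0("yb", l), gY[[l]]$b, netY[[l]]$b, ep)
      }
    }
    aX <- .mlpForward(netX, X)
    aY <- .mlpForward(netY, Y)
    structure(list(
      loss = loss,
      embedding = aX[[bnAct]],
      embedding_y = aY[[bnAct]],
      final_loss_x = mean((aX[[length(aX)]] - Y)^2),
      final_loss_y = mean((aY[[length(aY)]] - X)^2),
      widths = widths, epochs = epochs, learning_rate = learningRate,
      seed = seed), class = "autoencoderResult")
  })
}

#' Class separation of a 2-D embedding
#'
#' AUROC of the Fisher linear-discriminant score of the embedding - the
#' statistic used to judge whether the autoencoder bottleneck separates
#' FRI from control.
#'
#' @param embedding samples x 2 matrix.
#' @param labels binary labels (1 = FRI).
#' @return AUROC in [0, 1].
#' @export
embeddingSeparation <- function(embedding, labels) {
  E <- as.matrix(embedding)
  y <- as.integer(labels)
  mu1 <- colMeans(E[y == 1, , drop = FALSE])
  mu0 <- colMeans(E[y == 0, , drop = FALSE])
  R <- E
  R[y == 1, ] <- sweep(E[y == 1, , drop = FALSE], 2, mu1)
  R[y == 0, ] <- sweep(E[y == 0, , drop = FALSE], 2, mu0)
  W <- crossprod(R) / (nrow(E) - 2) + diag(1e-10, ncol(E))
  w <- solve(W, mu1 - mu0)
  aurocScore(drop(E %*% w), y)
}
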
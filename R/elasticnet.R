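# Sparse elastic-net logistic classifier. The l1/l2-penalized negative
# Bernoulli log-likelihood is minimized by cyclic coordinate descent
# (compiled); the lambda path is walked from heavy to light regularization
# and truncated before the number of nonzero coefficients would exceed the
# hard cap (default 50); among admissible path points the one with the best
# in-sample deviance is kept.

#' Elastic-net fit configuration
#'
#' @param alpha l1/l2 mixing in [0, 1]; 1 = lasso, 0 = ridge.
#' @param nlambda number of (log-spaced, decreasing) path points.
#' @param lambda_min_ratio smallest path lambda relative to the
#'   data-derived lambda_max.
#' @param max_nonzero hard cap on nonzero coefficients (default 50).
#' @param tol convergence tolerance on the largest coefficient update.
#' @param maxit maximum coordinate-descent sweeps per lambda.
#' @return list of class \code{"fitConfig"}.
#' @export
fitConfig <- function(alpha = 0.5, nlambda = 20L, lambda_min_ratio = 1e-3,
                      max_nonzero = 50L, tol = 1e-7, maxit = 1000L) {
  if (alpha < 0 || alpha > 1) stop("config error: alpha must be in [0, 1]")
  if (tol <= 0) stop("config error: tolerance must be > 0")
  if (max_nonzero < 1) stop("config error: max_nonzero must be >= 1")
  structure(as.list(environment()), class = "fitConfig")
}

#' Penalized logistic objective
#'
#' The quantity the fit minimizes: mean negative Bernoulli log-likelihood
#' plus \code{lambda * (alpha * sum(|beta|) + (1-alpha)/2 * sum(beta^2))}.
#' Exposed for oracle comparisons and diagnostics.
#'
#' @param X features (on the scale the coefficients refer to).
#' @param y binary labels.
#' @param intercept,beta model parameters.
#' @param lambda,alpha penalty.
#' @return the objective value.
#' @export
enetObjective <- function(X, y, intercept, beta, lambda, alpha) {
  eta <- drop(intercept + X %*% beta)
  nll <- mean(ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta))) - y * eta)
  nll + lambda * (alpha * sum(abs(beta)) + 0.5 * (1 - alpha) * sum(beta^2))
}

#' Fit the capped elastic-net logistic classifier
#'
#' Features are standardized to zero mean / unit variance internally
#' (coefficients are reported on the standardized scale; prediction applies
#' the stored standardization). The lambda grid is derived from the data:
#' \code{lambda_max} is the smallest penalty at which all coefficients are
#' zero, and the grid descends log-uniformly from there. The path stops
#' before the nonzero count would exceed \code{max_nonzero}; the admissible
#' point with the smallest in-sample deviance is selected.
#'
#' @param x a \linkS4class{FeatureMatrix} or samples x features matrix.
#' @param y binary labels (1 = FRI); taken from annotations when \code{x}
#'   is a \code{FeatureMatrix}.
#' @param config a \code{\link{fitConfig}} (or compatible list, e.g. the
#'   \code{$fit} section of a \code{\link{runConfig}}).
#' @param lambda optional fixed lambda value(s) overriding the automatic
#'   grid (still subject to the cap rule).
#' @return a fitted \linkS4class{ElasticNetModel}.
#' @export
enetFit <- function(x, y = NULL, config = fitConfig(), lambda = NULL) {
  isFM <- is(x, "FeatureMatrix")
  X <- if (isFM) features(x) else as.matrix(x)
  if (is.null(y)) {
    if (!isFM) stop("labels required for a plain matrix")
    y <- classLabels(x)
  }
  y <- as.numeric(y)
  if (length(unique(y)) < 2)
    stop("value error: both classes required to fit")
  if (min(table(y)) < 2)
    stop("value error: >= 2 samples per class required")
  n <- nrow(X); p <- ncol(X)
  ctr <- colMeans(X)
  scl <- sqrt(.colVars(X) * (n - 1) / n)     # population SD, so mean x^2 = 1
  if (any(scl <= 0))
    stop("value error: constant feature column (standardization guard)")
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
  alpha <- config$alpha
  if (is.null(lambda)) {
    # smallest lambda with an all-zero solution (alpha floored as in the
    # usual path construction so ridge-like fits still get a finite grid)
    ybar <- mean(y)
    g0 <- abs(crossprod(Xs, y - ybar)) / n
    lambdaMax <- max(g0) / max(alpha, 1e-3)
    lambda <- exp(seq(log(lambdaMax), log(lambdaMax * config$lambda_min_ratio),
                      length.out = config$nlambda))
  } else {
    lambda <- sort(as.numeric(lambda), decreasing = TRUE)
  }
  cap <- config$max_nonzero
  # the path is explored at a loose tolerance (selection needs only the
  # nonzero counts and deviances); the selected point is then refit to the
  # configured tolerance from a warm start
  pathTol <- max(config$tol, 1e-4)
  fitp <- .cpp_enet_path(Xs, y, lambda, alpha, pathTol, config$maxit,
                         as.integer(cap))
  lambda <- lambda[seq_len(fitp$fitted)]       # path stops once over the cap
  if (any(fitp$iters < 0))
    stop("convergence error: coordinate descent did not converge (",
         "lambda index ", which(fitp$iters < 0)[1], ", maxit ", config$maxit,
         ", tol ", pathTol, ")")
  admissible <- which(fitp$nonzero <= cap)
  if (!length(admissible))
    stop("value error: no admissible path point under the nonzero cap")
  sel <- admissible[which.min(fitp$nll[admissible])]
  repeat {
    refit <- .cpp_enet_single(Xs, y, lambda[sel], alpha, config$tol,
                              config$maxit, fitp$beta[, sel], fitp$b0[sel])
    if (!refit$converged)
      stop("convergence error: coordinate descent did not converge (",
           "selected lambda, maxit ", config$maxit, ", tol ", config$tol, ")")
    # tightening the fit can flip a coefficient across zero; honor the cap
    if (sum(refit$beta != 0) <= cap || sel == 1) break
    sel <- sel - 1L
  }
  beta <- refit$beta
  fitp$b0[sel] <- refit$b0
  ids <- colnames(X) %||% sprintf("f%d", seq_len(p))
  new("ElasticNetModel",
      intercept = fitp$b0[sel], coefficients = as.numeric(beta),
      featureIds = ids, lambda = lambda[sel], alpha = alpha,
      center = as.numeric(ctr), scale = as.numeric(scl),
      nonzeroCount = as.integer(sum(beta != 0)),
      maxNonzero = as.integer(cap),
      path = list(lambda = lambda, nonzero = as.integer(fitp$nonzero),
                  nll = as.numeric(fitp$nll), selected = sel))
}

#' @rdname predictProba
#' @export
setMethod("predictProba", "ElasticNetModel", function(object, newdata) {
  X <- if (is(newdata, "FeatureMatrix")) features(newdata) else as.matrix(newdata)
  if (!is.null(colnames(X))) {
    miss <- setdiff(object@featureIds, colnames(X))
    if (length(miss))
      stop("alignment error: missing feature(s): ",
           paste(utils::head(miss, 5), collapse = ", "))
    X <- X[, object@featureIds, drop = FALSE]
  } else if (ncol(X) != length(object@coefficients))
    stop("alignment error: feature count mismatch")
  Xs <- sweep(sweep(X, 2, object@center), 2, object@scale, `/`)
  eta <- drop(object@intercept + Xs %*% object@coefficients)
  stats::plogis(eta)
})
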
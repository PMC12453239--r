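# Independent slow optimizer for the penalized logistic objective:
# proximal-gradient (ISTA) with backtracking, sharing only the objective
# definition with the package implementation.
istaEnet <- function(X, y, lambda, alpha, iters = 200000, tolObj = 1e-12) {
  n <- nrow(X); p <- ncol(X)
  b0 <- 0; beta <- rep(0, p)
  step <- 1 / (max(colSums(X^2)) / (4 * n) * p + lambda * (1 - alpha) + 0.25)
  obj <- function(b0, beta) enetObjective(X, y, b0, beta, lambda, alpha)
  cur <- obj(b0, beta)
  for (it in seq_len(iters)) {
    eta <- b0 + drop(X %*% beta)
    pr <- 1 / (1 + exp(-eta))
    g0 <- mean(pr - y)
    g <- drop(crossprod(X, pr - y)) / n + lambda * (1 - alpha) * beta
    s <- step
    repeat {
      nb0 <- b0 - s * g0
      nb <- beta - s * g
      nb <- sign(nb) * pmax(abs(nb) - s * lambda * alpha, 0)
      nob <- obj(nb0, nb)
      if (nob <= cur + 1e-14 || s < 1e-12) break
      s <- s / 2
    }
    if (cur - nob < tolObj && it > 100) { b0 <- nb0; beta <- nb; cur <- nob; break }
    b0 <- nb0; beta <- nb; cur <- nob
  }
  list(b0 = b0, beta = beta, objective = cur)
}

randomInstance <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  X <- scale(X) * sqrt(n / (n - 1))   # unit population SD, as the fit uses
  beta <- rnorm(p) * rbinom(p, 1, 0.5)
  y <- rbinom(n, 1, plogis(drop(X %*% beta) * 0.8))
  if (length(unique(y)) < 2 || min(table(y)) < 2) return(NULL)
  list(X = X, y = y)
}
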
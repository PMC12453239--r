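# Bootstrap performance estimation and fixed-effect pooling. The resampling
# unit is the matched FRI/control pair (preserving the paired design); each
# bootstrap draw trains on the in-bag samples and is evaluated on the
# out-of-bag samples. A session is B such draws under one seed; sessions are
# repeated independently under varying seeds and pooled by inverse-variance
# fixed-effect meta-analysis.

#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' Mean over all positive/negative pairs of the indicator that the positive
#' outranks the negative, counting ties as 1/2.
#'
#' @param scores numeric classifier scores.
#' @param labels binary labels (1 = positive).
#' @return the AUROC in [0, 1].
#' @export
aurocScore <- function(scores, labels) {
  pos <- labels == 1L
  nPos <- sum(pos); nNeg <- sum(!pos)
  if (nPos == 0 || nNeg == 0)
    stop("value error: both classes required for AUROC")
  r <- rank(scores)                      # average ranks implement the tie rule
  (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Sensitivity and specificity at a fixed probability threshold
#'
#' @param scores predicted positive-class probabilities.
#' @param labels binary labels (1 = positive).
#' @param threshold classify positive when score > threshold (default 0.5).
#' @return named numeric: \code{sensitivity} = TP/(TP+FN),
#'   \code{specificity} = TN/(TN+FP).
#' @export
sensSpec <- function(scores, labels, threshold = 0.5) {
  pos <- labels == 1L
  if (!any(pos) || all(pos))
    stop("value error: both classes required")
  pred <- scores > threshold
  c(sensitivity = sum(pred & pos) / sum(pos),
    specificity = sum(!pred & !pos) / sum(!pos))
}

#' One bootstrap training session
#'
#' Draws \code{B} pair-level bootstrap resamples; per draw, optionally
#' screens features on the in-bag samples only (\code{filterScope =
#' "resample"}, the default, which keeps out-of-bag evaluation unbiased),
#' fits the capped elastic net on the in-bag samples, and scores the
#' out-of-bag samples. Draws whose out-of-bag set is empty are redrawn (the
#' count is reported). Draws in which no feature passes the screen fall
#' back to a constant-prevalence model (AUROC 0.5 by the tie rule).
#'
#' @param x a \linkS4class{FeatureMatrix} (unfiltered when
#'   \code{filterScope = "resample"}).
#' @param config a \code{\link{runConfig}} (uses \code{$fit},
#'   \code{$filter}, \code{$bootstrap} sections).
#' @param seed session seed; all of the session's randomness flows from it.
#' @param B bootstrap draws in this session.
#' @param filterScope \code{"resample"}, or \code{"none"} when screening
#'   already happened upstream.
#' @return list of class \code{"sessionResult"}: per-draw metrics,
#'   session mean \code{m} and variance-of-mean \code{v} per metric,
#'   per-draw selected feature ids, redraw/fallback counts, the seed.
#' @export
runSession <- function(x, config = runConfig(), seed = 1L,
                       B = config$bootstrap$resamples,
                       filterScope = config$filter$scope) {
  stopifnot(is(x, "FeatureMatrix"))
  X <- features(x)
  y <- classLabels(x)
  pairs <- as.character(sampleInfo(x)$pair_id)
  upairs <- unique(pairs)
  if (length(upairs) < 2) stop("value error: >= 2 pairs required")
  if (any(!is.finite(X))) stop("value error: non-finite feature values")
  fitCfg <- config$fit
  thr <- config$bootstrap$threshold
  dThr <- config$filter$d_threshold
  maxRedraw <- config$bootstrap$max_redraws %||% 100L
  doFilter <- identical(filterScope, "resample")

  metrics <- matrix(NA_real_, B, 3,
                    dimnames = list(NULL, c("auroc", "sensitivity", "specificity")))
  selected <- vector("list", B)
  redraws <- 0L; fallbacks <- 0L
  .withSeed(seed, {
    for (b in seq_len(B)) {
      oobRows <- integer()
      for (try in seq_len(maxRedraw)) {
        drawn <- sample(upairs, length(upairs), replace = TRUE)
        inRows <- unlist(lapply(drawn, function(p) which(pairs == p)),
                         use.names = FALSE)
        oobRows <- which(!pairs %in% drawn)
        # matched pairs: a nonempty out-of-bag set always holds both classes
        if (length(oobRows) && length(unique(y[oobRows])) == 2) break
        redraws <- redraws + 1L
        oobRows <- integer()
      }
      if (!length(oobRows))
        stop("resampling error: no valid out-of-bag set after ",
             maxRedraw, " redraws")
      Xin <- X[inRows, , drop = FALSE]; yin <- y[inRows]
      keep <- .colVars(Xin) > 0
      Xin <- Xin[, keep, drop = FALSE]
      sel <- character()
      probs <- NULL
      if (doFilter) {
        eff <- .columnEffects(Xin, yin)
        pass <- !is.na(eff$d) & abs(eff$d) > dThr
        if (!any(pass)) {
          fallbacks <- fallbacks + 1L
          probs <- rep(mean(yin), length(oobRows))
        } else Xin <- Xin[, pass, drop = FALSE]
      }
      if (is.null(probs)) {
        model <- enetFit(Xin, yin, fitCfg)
        sel <- selectedFeatures(model)
        probs <- predictProba(model, X[oobRows, colnames(Xin), drop = FALSE])
      }
      yo <- y[oobRows]
      metrics[b, "auroc"] <- aurocScore(probs, yo)
      metrics[b, c("sensitivity", "specificity")] <- sensSpec(probs, yo, thr)
      selected[[b]] <- sel
    }
  })
  m <- colMeans(metrics)
  v <- apply(metrics, 2, stats::var) / B    # SE^2 of the session mean
  structure(list(seed = seed, B = B, metrics = as.data.frame(metrics),
                 m = m, v = v, selected = selected,
                 redraws = redraws, fallbacks = fallbacks),
            class = "sessionResult")
}

#' Run repeated independent bootstrap sessions
#'
#' @param x a \linkS4class{FeatureMatrix}.
#' @param config a \code{\link{runConfig}}; \code{config$seed} spawns the
#'   per-session seeds \code{seed + 1:S} (all recorded).
#' @param S number of sessions.
#' @param filterScope see \code{\link{runSession}}.
#' @return list of \code{sessionResult}s with the seed vector as attribute
#'   \code{"seeds"}.
#' @export
runBootstrap <- function(x, config = runConfig(),
                         S = config$bootstrap$sessions,
                         filterScope = config$filter$scope) {
  seeds <- as.integer(config$seed) + seq_len(S)
  sessions <- lapply(seeds, function(s)
    runSession(x, config, seed = s, filterScope = filterScope))
  attr(sessions, "seeds") <- seeds
  sessions
}

#' Fixed-effect pooling of bootstrap sessions
#'
#' Per metric, sessions are combined by inverse-variance weighting:
#' pooled mean \code{sum(m/v) / sum(1/v)} with
#' \code{CI95 = mean +/- 1.96 / sqrt(sum(1/v))} (clipped to [0, 1]);
#' \code{pooling = "mean"} uses the unweighted session mean with a normal
#' CI from the between-session SD instead.
#'
#' @param sessions list of \code{sessionResult}s.
#' @param pooling \code{"ivw"} (default) or \code{"mean"}.
#' @return a \linkS4class{PooledMetrics}.
#' @export
poolSessions <- function(sessions, pooling = c("ivw", "mean")) {
  pooling <- match.arg(pooling)
  if (length(sessions) < 2) stop("value error: >= 2 sessions required")
  mets <- names(sessions[[1]]$m)
  rows <- lapply(mets, function(met) {
    m <- vapply(sessions, function(s) s$m[[met]], numeric(1))
    v <- vapply(sessions, function(s) s$v[[met]], numeric(1))
    if (any(v <= 0))
      stop("value error: degenerate session (zero variance) for ", met)
    if (pooling == "ivw") {
      wsum <- sum(1 / v)
      mu <- sum(m / v) / wsum
      se <- 1 / sqrt(wsum)
    } else {
      mu <- mean(m)
      se <- stats::sd(m) / sqrt(length(m))
    }
    data.frame(metric = met, mean = mu, sd = stats::sd(m),
               ci_lo = max(0, mu - 1.96 * se),
               ci_hi = min(1, mu + 1.96 * se))
  })
  new("PooledMetrics", estimates = do.call(rbind, rows),
      nSessions = length(sessions), pooling = pooling)
}

#' Feature selection frequencies across all resamples
#'
#' @param sessions list of \code{sessionResult}s.
#' @param topK size of the reported top list (default 40).
#' @return data.frame (\code{feature}, \code{frequency}) sorted by
#'   decreasing frequency, ties broken alphabetically by feature id;
#'   attribute \code{"top"} holds the top-\code{topK} ids.
#' @export
rankFeatures <- function(sessions, topK = 40L) {
  all <- unlist(lapply(sessions, function(s) unlist(s$selected)),
                use.names = FALSE)
  total <- sum(vapply(sessions, function(s) s$B, numeric(1)))
  if (!length(all)) {
    out <- data.frame(feature = character(), frequency = numeric())
    attr(out, "top") <- character()
    return(out)
  }
  tab <- table(all)
  out <- data.frame(feature = names(tab),
                    frequency = as.numeric(tab) / total,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "top") <- utils::head(out$feature, topK)
  out
}
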
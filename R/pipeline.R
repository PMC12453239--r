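# End-to-end analysis drivers. The FTIR and MS branches share one
# classification code path (screening -> capped elastic net -> pair-level
# bootstrap -> fixed-effect pooling); the MS branch simply skips the
# spectral stages and enters on log abundance ratios.

#' Shared classification stage
#'
#' Runs effect-size screening and the bootstrapped capped elastic net on
#' any sample-level feature matrix, then pools sessions.
#'
#' @param fm a \linkS4class{FeatureMatrix}.
#' @param config a \code{\link{runConfig}}.
#' @return list with \code{pooled} (\linkS4class{PooledMetrics}),
#'   \code{ranking} (selection-frequency table, attribute \code{"top"}),
#'   \code{sessions} (per-session records), \code{session_seeds},
#'   \code{filter} (the global screening report when
#'   \code{config$filter$scope == "global"}, else \code{NULL}) and
#'   \code{config}.
#' @export
classifyFeatures <- function(fm, config = runConfig()) {
  stopifnot(is(fm, "FeatureMatrix"))
  validateRunConfig(config)
  filterReport <- NULL
  if (identical(config$filter$scope, "global")) {
    flt <- filterFeatures(fm, threshold = config$filter$d_threshold)
    fm <- flt$filtered
    filterReport <- flt$result
    scope <- "none"
  } else scope <- "resample"
  sessions <- runBootstrap(fm, config, filterScope = scope)
  pooled <- poolSessions(sessions, pooling = config$bootstrap$pooling)
  ranking <- rankFeatures(sessions)
  list(pooled = pooled, ranking = ranking, sessions = sessions,
       session_seeds = attr(sessions, "seeds"),
       filter = filterReport, config = unclass(config))
}

#' Full FTIR branch
#'
#' Spectral preprocessing (\code{\link{preprocessSpectra}}) followed by the
#' shared classification stage.
#'
#' @param spectra a \linkS4class{SpectralDataset}.
#' @param config a \code{\link{runConfig}}.
#' @return as \code{\link{classifyFeatures}}, plus \code{features} (the
#'   preprocessed \linkS4class{FeatureMatrix}).
#' @export
ftirPipeline <- function(spectra, config = runConfig()) {
  fm <- preprocessSpectra(spectra, config)
  out <- classifyFeatures(fm, config)
  out$features <- fm
  out
}

#' Full mass-spectrometry branch
#'
#' Protein abundance ratios are natural-log transformed (they are
#' multiplicative quantities); Savitzky-Golay filtering and the DCT are not
#' applied, MS features forming no continuous correlated spectrum. The
#' remaining stages are identical to the FTIR branch.
#'
#' @param proteins a \linkS4class{ProteinTable}.
#' @param config a \code{\link{runConfig}}.
#' @return as \code{\link{classifyFeatures}}, plus \code{features}.
#' @export
msPipeline <- function(proteins, config = runConfig()) {
  stopifnot(is(proteins, "ProteinTable"))
  fm <- FeatureMatrix(log(ratios(proteins)),
                      featureIds = proteinIds(proteins),
                      samples = sampleInfo(proteins),
                      metadata = list(transform = "natural log of abundance ratio"))
  out <- classifyFeatures(fm, config)
  out$features <- fm
  out
}

#' Assemble the serializable results record
#'
#' Reduces a pipeline result to the reproducibility record written by
#' \code{\link{writeResults}}: pooled metrics, per-session metrics,
#' selection ranking, session seeds and the full configuration.
#'
#' @param out a \code{\link{classifyFeatures}}-shaped result list.
#' @return a plain list ready for JSON serialization.
#' @export
resultsRecord <- function(out) {
  list(
    pooled = out$pooled,
    sessions = lapply(out$sessions, function(s)
      list(seed = s$seed, B = s$B, m = as.list(s$m), v = as.list(s$v),
           metrics = s$metrics, redraws = s$redraws,
           fallbacks = s$fallbacks)),
    ranking = out$ranking,
    top_features = attr(out$ranking, "top"),
    session_seeds = out$session_seeds,
    config = out$config
  )
}
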
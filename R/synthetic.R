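# Synthetic paired-cohort generator. Emulates the statistical structure the
# analysis assumes: 13 matched FRI/control pairs, three replicate dried-film
# spectra per sample built from Gaussian plasma bands plus a thiocyanate
# internal-standard peak, baseline drift and channel noise, and a log-normal
# protein abundance-ratio table with a planted differential subset.

.defaultPeaks <- function() {
  # nominal plasma-film bands: centers/widths in cm^-1, amplitudes in a.u.
  data.frame(
    center = c(1080, 1240, 1400, 1545, 1650, 2850, 2925, 2960, 3300),
    width  = c(  30,   30,   25,   25,   25,   15,   18,   12,   80),
    amp    = c(0.40, 0.35, 0.45, 0.80, 1.00, 0.25, 0.35, 0.30, 0.70),
    cv     = rep(0.15, 9)
  )
}

#' Configuration of the synthetic paired-cohort generator
#'
#' @param n_pairs matched FRI/control pairs (default 13, the study design).
#' @param wn_min,wn_max,wn_step wavenumber grid in cm^-1 (default 400..4000
#'   at 4 cm^-1, the nominal spectral resolution).
#' @param peaks data.frame with \code{center}, \code{width} (Gaussian SD),
#'   \code{amp} (mean amplitude) and \code{cv} (between-sample amplitude
#'   coefficient of variation) per plasma band.
#' @param kscn_center,kscn_width,kscn_amp,kscn_cv internal-standard
#'   (thiocyanate C#N stretch) peak; its amplitude is independent of class.
#' @param replicate_cv replicate-level amplitude jitter (pipetting).
#' @param baseline_degree,baseline_amp random polynomial baseline drift per
#'   replicate.
#' @param noise_sd i.i.d. channel noise SD (a.u.).
#' @param pair_icc fraction of between-sample log-amplitude variance shared
#'   within a matched pair (matching on age/fracture region induces
#'   within-pair similarity).
#' @param effect_peaks indices into \code{peaks} whose amplitudes carry the
#'   class effect.
#' @param effect_size target Cohen's d of the planted shift on affected
#'   log-amplitudes (0 = exchangeable null).
#' @param n_proteins,n_diff_proteins protein table size and planted
#'   differential subset (defaults 1000 and 32, the scale reported for
#'   plasma proteomics of this contrast).
#' @param protein_delta planted log-scale shift of differential proteins in
#'   FRI, in units of the between-sample log SD.
#' @param protein_cv between-sample coefficient of variation of ratios.
#' @param seed integer RNG seed.
#' @return a validated list of class \code{"syntheticConfig"}.
#' @export
syntheticConfig <- function(n_pairs = 13L,
                            wn_min = 400, wn_max = 4000, wn_step = 4,
                            peaks = .defaultPeaks(),
                            kscn_center = 2060, kscn_width = 15,
                            kscn_amp = 0.6, kscn_cv = 0.05,
                            replicate_cv = 0.02,
                            baseline_degree = 2L, baseline_amp = 0.03,
                            noise_sd = 0.004,
                            pair_icc = 0.3,
                            effect_peaks = c(4L, 5L, 7L),
                            effect_size = 0,
                            n_proteins = 1000L, n_diff_proteins = 32L,
                            protein_delta = 0.8, protein_cv = 0.25,
                            seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_pairs < 2) stop("value error: n_pairs must be >= 2")
  if (cfg$effect_size < 0) stop("value error: effect_size must be >= 0")
  if (length(cfg$effect_peaks) &&
      (min(cfg$effect_peaks) < 1 || max(cfg$effect_peaks) > nrow(cfg$peaks)))
    stop("value error: effect_peaks must index rows of peaks")
  if (cfg$n_diff_proteins > cfg$n_proteins)
    stop("value error: n_diff_proteins exceeds n_proteins")
  stopifnot(cfg$wn_step > 0, cfg$noise_sd >= 0, cfg$kscn_amp > 0,
            all(cfg$peaks$amp > 0), all(cfg$peaks$width > 0),
            cfg$pair_icc >= 0, cfg$pair_icc <= 1)
  structure(cfg, class = "syntheticConfig")
}

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

.gauss <- function(x, center, width) exp(-0.5 * ((x - center) / width)^2)

#' Ground truth planted by a synthetic configuration
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @return list with \code{affected_channels} (indices of grid channels
#'   within 2 SD of an affected band center), \code{affected_peaks} and
#'   \code{affected_proteins} (ids). Deterministic in the configuration:
#'   independent of the seed.
#' @export
plantedTruth <- function(config) {
  w <- seq(config$wn_min, config$wn_max, by = config$wn_step)
  idx <- integer()
  for (j in config$effect_peaks) {
    c0 <- config$peaks$center[j]; wd <- config$peaks$width[j]
    idx <- union(idx, which(abs(w - c0) <= 2 * wd))
  }
  prot <- sprintf("prot%04d", seq_len(config$n_proteins))
  list(affected_channels = sort(idx),
       affected_peaks = as.integer(config$effect_peaks),
       affected_proteins = prot[seq_len(config$n_diff_proteins)])
}

#' Generate a paired synthetic FTIR + proteomics dataset
#'
#' Draws sample-level band amplitudes log-normally (with a within-pair
#' shared component), shifts affected-band log-amplitudes of FRI samples by
#' \code{effect_size} between-sample log SDs, and renders three replicate
#' spectra per sample as Gaussian band mixtures plus internal-standard peak,
#' polynomial baseline drift and channel noise. Protein ratios are
#' log-normal with the first \code{n_diff_proteins} accessions mean-shifted
#' by \code{protein_delta} log SDs in FRI. Fully reproducible from the seed.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @return list with elements \code{spectra} (\linkS4class{SpectralDataset};
#'   its metadata holds the latent sample-level band amplitudes) and
#'   \code{proteins} (\linkS4class{ProteinTable}).
#' @export
generateDataset <- function(config) {
  stopifnot(inherits(config, "syntheticConfig"))
  .withSeed(config$seed, {
    np <- config$n_pairs
    w <- seq(config$wn_min, config$wn_max, by = config$wn_step)
    C <- length(w)
    samples <- data.frame(
      sample_id = c(sprintf("FRI%02d", seq_len(np)),
                    sprintf("CTL%02d", seq_len(np))),
      class = rep(c("FRI", "control"), each = np),
      pair_id = rep(sprintf("P%02d", seq_len(np)), 2),
      stringsAsFactors = FALSE
    )
    ns <- nrow(samples)
    pk <- config$peaks
    J <- nrow(pk)
    sigma <- sqrt(log(1 + pk$cv^2))            # log-normal SD per band
    # within-pair shared + sample-specific log-amplitude components
    zPair <- matrix(stats::rnorm(np * J), np, J)
    zSamp <- matrix(stats::rnorm(ns * J), ns, J)
    pairIdx <- match(samples$pair_id, sprintf("P%02d", seq_len(np)))
    z <- sqrt(config$pair_icc) * zPair[pairIdx, , drop = FALSE] +
      sqrt(1 - config$pair_icc) * zSamp
    logAmp <- sweep(sweep(z, 2, sigma, `*`), 2, log(pk$amp), `+`)
    if (config$effect_size > 0 && length(config$effect_peaks)) {
      isFRI <- samples$class == "FRI"
      for (j in config$effect_peaks)
        logAmp[isFRI, j] <- logAmp[isFRI, j] + config$effect_size * sigma[j]
    }
    amp <- exp(logAmp)                          # samples x bands
    rownames(amp) <- samples$sample_id
    colnames(amp) <- sprintf("band_%d", pk$center)

    basis <- vapply(seq_len(J),
                    function(j) .gauss(w, pk$center[j], pk$width[j]),
                    numeric(C))                 # C x J
    kscnShape <- .gauss(w, config$kscn_center, config$kscn_width)
    tgrid <- 2 * (w - config$wn_min) / (config$wn_max - config$wn_min) - 1

    nrep <- 3L
    R <- ns * nrep
    A <- matrix(0, R, C)
    repOf <- character(R)
    repIds <- character(R)
    r <- 0L
    for (s in seq_len(ns)) {
      for (k in seq_len(nrep)) {
        r <- r + 1L
        jit <- exp(stats::rnorm(J, 0, sqrt(log(1 + config$replicate_cv^2))))
        spec <- drop(basis %*% (amp[s, ] * jit))
        kamp <- config$kscn_amp *
          exp(stats::rnorm(1, 0, sqrt(log(1 + config$kscn_cv^2))))
        base <- numeric(C)
        for (d in 0:config$baseline_degree)
          base <- base + stats::rnorm(1, 0, 1) / (d + 1) * tgrid^d
        spec <- spec + kamp * kscnShape + config$baseline_amp * base +
          stats::rnorm(C, 0, config$noise_sd)
        A[r, ] <- spec
        repOf[r] <- samples$sample_id[s]
        repIds[r] <- sprintf("%s_r%d", samples$sample_id[s], k)
      }
    }
    rownames(A) <- repIds
    spectra <- SpectralDataset(w, A, repOf, samples,
                               metadata = list(config = unclass(config),
                                               band_amplitudes = amp))

    P <- config$n_proteins
    sigP <- sqrt(log(1 + config$protein_cv^2))
    zP <- sqrt(0.2) * matrix(stats::rnorm(np * P), np, P)[pairIdx, , drop = FALSE] +
      sqrt(0.8) * matrix(stats::rnorm(ns * P), ns, P)
    logRatio <- sigP * zP
    nd <- config$n_diff_proteins
    if (nd > 0 && config$protein_delta != 0) {
      isFRI <- samples$class == "FRI"
      logRatio[isFRI, seq_len(nd)] <-
        logRatio[isFRI, seq_len(nd)] + config$protein_delta * sigP
    }
    prot <- ProteinTable(exp(logRatio), sprintf("prot%04d", seq_len(P)),
                         samples,
                         metadata = list(config = unclass(config)))
    list(spectra = spectra, proteins = prot)
  })
}
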
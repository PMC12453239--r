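# Run configuration: every tunable of every stage lives here, flows into
# results records, and round-trips through YAML unchanged, so a recorded
# config + seed fully determines a run.

#' Build a run configuration
#'
#' Returns the default configuration for the full dual-modality analysis,
#' with any element overridden by name. Defaults follow common FTIR
#' chemometrics practice where the method leaves a choice open; all are
#' recorded in every results file.
#'
#' @param ... named overrides of top-level sections or, via nested lists,
#'   individual values (e.g. \code{fit = list(alpha = 1)} replaces only
#'   \code{alpha}).
#' @return a validated nested list of class \code{"runConfig"}.
#' @export
runConfig <- function(...) {
  cfg <- list(
    preprocess = list(
      kscn_band = c(2000, 2150),      # cm^-1, internal-standard band
      sg_window = 11L,                # Savitzky-Golay window (channels, odd)
      sg_polyorder = 3L,
      sg_deriv = 0L,
      positivity_epsilon_rel = 1e-8,  # clip at eps * max(|row|) before logs
      dct_drop_k = 0L,                # leading DCT frequencies dropped
      near_zero_var_rel = 1e-8        # relative across-sample variance floor
    ),
    filter = list(
      d_threshold = 0.5,              # retain |Cohen's d| > threshold
      scope = "global"                # "global" (screen once, upstream;
                                      # optimistic, see vignette) or
                                      # "resample" (inside each draw)
    ),
    fit = list(
      alpha = 0.5,                    # l1/l2 mix; 1 = lasso, 0 = ridge
      nlambda = 20L,
      lambda_min_ratio = 1e-3,
      max_nonzero = 50L,              # hard cap on used coefficients
      tol = 1e-7,
      maxit = 1000L
    ),
    bootstrap = list(
      sessions = 100L,                # independent training sessions (S)
      resamples = 100L,               # bootstrap draws per session (B)
      pooling = "ivw",                # fixed-effect pooling: "ivw" or "mean"
      threshold = 0.5,                # probability cut for sens/spec
      max_redraws = 100L
    ),
    crossmodal = list(
      top_k = 8L,                     # per-modality feature pre-selection
      n_perm = 1000L,
      ae_widths = c(64L, 16L, 4L),    # encoder layer widths -> bottleneck 2
      ae_epochs = 2000L,
      ae_learning_rate = 0.01
    ),
    seed = 1L
  )
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("unknown config section: ", nm)
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      bad <- setdiff(names(over[[nm]]), names(cfg[[nm]]))
      if (length(bad)) stop("unknown config field: ", nm, "$", bad[1])
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else cfg[[nm]] <- over[[nm]]
  }
  validateRunConfig(cfg)
  structure(cfg, class = "runConfig")
}

#' Validate a run configuration
#'
#' @param cfg a config list.
#' @return invisibly \code{TRUE}; stops with a config error otherwise.
#' @export
validateRunConfig <- function(cfg) {
  p <- cfg$preprocess
  if (p$sg_window %% 2 == 0)
    stop("config error: sg_window must be odd")
  if (p$sg_window <= p$sg_polyorder)
    stop("config error: sg_window must exceed sg_polyorder")
  if (length(p$kscn_band) != 2 || p$kscn_band[1] >= p$kscn_band[2])
    stop("config error: kscn_band must be an increasing [lo, hi]")
  f <- cfg$fit
  if (f$alpha < 0 || f$alpha > 1) stop("config error: alpha must be in [0,1]")
  if (f$tol <= 0) stop("config error: tolerance must be > 0")
  if (f$max_nonzero < 1) stop("config error: max_nonzero must be >= 1")
  if (!cfg$filter$scope %in% c("resample", "global"))
    stop("config error: filter scope must be 'resample' or 'global'")
  if (!cfg$bootstrap$pooling %in% c("ivw", "mean"))
    stop("config error: pooling must be 'ivw' or 'mean'")
  if (cfg$filter$d_threshold < 0)
    stop("config error: d_threshold must be >= 0")
  invisible(TRUE)
}

#' Write a run configuration to YAML
#'
#' @param cfg a \code{runConfig}.
#' @param path output YAML path.
#' @return \code{path}, invisibly.
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' @param path YAML path.
#' @return a validated \code{runConfig}; round-trips written configs
#'   value-identically.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- runConfig()
  for (sec in names(cfg))
    if (is.list(cfg[[sec]]) && is.list(base[[sec]])) {
      # restore integer storage where the defaults are integer
      for (nm in names(cfg[[sec]]))
        if (nm %in% names(base[[sec]]) && is.integer(base[[sec]][[nm]]))
          cfg[[sec]][[nm]] <- as.integer(cfg[[sec]][[nm]])
    }
  if (!is.null(cfg$seed)) cfg$seed <- as.integer(cfg$seed)
  validateRunConfig(cfg)
  structure(cfg, class = "runConfig")
}
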
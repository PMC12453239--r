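# Small in-code fixtures shared across test files.

toySamples <- function(nPairs = 3) {
  data.frame(
    sample_id = c(sprintf("FRI%02d", seq_len(nPairs)),
                  sprintf("CTL%02d", seq_len(nPairs))),
    class = rep(c("FRI", "control"), each = nPairs),
    pair_id = rep(sprintf("P%02d", seq_len(nPairs)), 2),
    stringsAsFactors = FALSE
  )
}

# deterministic little spectral dataset: nPairs pairs x 3 replicates x C channels
toySpectra <- function(nPairs = 3, C = 24, seed = 1) {
  set.seed(seed)
  smp <- toySamples(nPairs)
  ns <- nrow(smp)
  w <- seq(1000, 1000 + 10 * (C - 1), by = 10)
  A <- matrix(abs(rnorm(3 * ns * C, mean = 1, sd = 0.2)), 3 * ns, C)
  repOf <- rep(smp$sample_id, each = 3)
  rownames(A) <- paste0(repOf, "_r", rep(1:3, ns))
  SpectralDataset(w, A, repOf, smp)
}

# small, quick synthetic configuration for pipeline-level tests
quickConfig <- function(...) {
  syntheticConfig(wn_step = 16, n_proteins = 120L, n_diff_proteins = 8L, ...)
}
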
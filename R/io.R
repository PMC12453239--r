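# Tabular readers/writers. The pipeline starts from exported text tables:
# spectra as wide CSV/TSV (wavenumber column + one column per replicate
# well), proteins as TSV (samples x accessions), metadata as CSV keyed by
# sample_id. Vendor instrument binaries and raw MS files are out of scope.

.readTable <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Read a sample metadata table
#'
#' @param path CSV with columns \code{sample_id}, \code{class} (\code{FRI}
#'   or \code{control}), \code{pair_id} and \code{replicates} (semicolon-
#'   separated replicate well ids, matching spectra column headers).
#' @return data.frame with those columns; \code{replicates} parsed to a list
#'   column is left as the raw string (see \code{\link{readSpectra}}).
#' @export
readMetadata <- function(path) {
  meta <- .readTable(path)
  need <- c("sample_id", "class", "pair_id")
  if (!all(need %in% colnames(meta)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("metadata error: duplicated sample_id")
  meta
}

#' Read replicate-level FTIR spectra
#'
#' The spectra file is a wide table: column 1 holds the wavenumber grid
#' (cm^-1, strictly increasing), each further column one replicate well's
#' absorbance, with the replicate id as header. The companion metadata table
#' assigns replicate wells to samples and samples to class/pair.
#'
#' @param path spectra CSV/TSV.
#' @param metadata metadata file path or a data.frame as returned by
#'   \code{\link{readMetadata}} (must include a \code{replicates} column).
#' @return a \linkS4class{SpectralDataset}; replicate row order follows the
#'   spectra file's column order, channel order is preserved.
#' @export
readSpectra <- function(path, metadata) {
  tab <- .readTable(path)
  if (ncol(tab) < 2) stop("format error: no replicate columns")
  w <- as.numeric(tab[[1]])
  if (any(!is.finite(w)) || any(diff(w) <= 0))
    stop("format error: wavenumber column must be finite and strictly increasing")
  A <- t(as.matrix(tab[, -1, drop = FALSE]))
  if (is.character(metadata)) metadata <- readMetadata(metadata)
  if (!"replicates" %in% colnames(metadata))
    stop("metadata error: 'replicates' column required to map wells to samples")
  repmap <- do.call(rbind, lapply(seq_len(nrow(metadata)), function(i) {
    reps <- trimws(strsplit(as.character(metadata$replicates[i]), ";")[[1]])
    data.frame(replicate = reps, sample_id = metadata$sample_id[i],
               stringsAsFactors = FALSE)
  }))
  wells <- rownames(A)
  unknown <- setdiff(wells, repmap$replicate)
  if (length(unknown))
    stop("metadata error: replicate well(s) with unknown sample id: ",
         paste(unknown, collapse = ", "))
  replicateOf <- repmap$sample_id[match(wells, repmap$replicate)]
  SpectralDataset(w, A, replicateOf,
                  metadata[, c("sample_id", "class", "pair_id")])
}

#' Write replicate-level FTIR spectra
#'
#' Inverse of \code{\link{readSpectra}} for the spectra table itself
#' (metadata is written separately with \code{\link{writeMetadata}}).
#'
#' @param dataset a \linkS4class{SpectralDataset}.
#' @param path output CSV/TSV path.
#' @return \code{path}, invisibly.
#' @export
writeSpectra <- function(dataset, path) {
  A <- absorbance(dataset)
  wells <- rownames(A)
  if (is.null(wells)) wells <- sprintf("rep%d", seq_len(nrow(A)))
  out <- data.frame(wavenumber = wavenumbers(dataset), check.names = FALSE)
  out[wells] <- as.data.frame(t(A))
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(format(out, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the metadata table for a dataset
#'
#' @param dataset a \linkS4class{SpectralDataset} or
#'   \linkS4class{ProteinTable}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeMetadata <- function(dataset, path) {
  smp <- as.data.frame(sampleInfo(dataset))
  if (is(dataset, "SpectralDataset")) {
    A <- absorbance(dataset)
    wells <- rownames(A)
    if (is.null(wells)) wells <- sprintf("rep%d", seq_len(nrow(A)))
    smp$replicates <- vapply(smp$sample_id, function(s)
      paste(wells[replicateOf(dataset) == s], collapse = ";"), character(1))
  }
  utils::write.csv(smp, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a protein abundance-ratio table
#'
#' @param path TSV; by default row 1 holds protein accessions (header), one
#'   row per sample, first column the sample id.
#' @param metadata metadata file path or data.frame (class/pair per sample).
#' @param proteinsAsRows set \code{TRUE} when the file is transposed
#'   (proteins as rows, samples as columns).
#' @return a \linkS4class{ProteinTable}; all ratios must be positive.
#' @export
readProteinTable <- function(path, metadata, proteinsAsRows = FALSE) {
  tab <- .readTable(path)
  ids <- as.character(tab[[1]])
  M <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(M) <- "double"
  rownames(M) <- ids
  if (proteinsAsRows) M <- t(M)
  if (anyDuplicated(colnames(M)))
    stop("format error: duplicated protein id")
  if (any(!is.finite(M)) || any(M <= 0))
    stop("value error: abundance ratios must be finite and > 0")
  if (is.character(metadata)) metadata <- readMetadata(metadata)
  miss <- setdiff(rownames(M), metadata$sample_id)
  if (length(miss))
    stop("metadata error: sample(s) without annotations: ",
         paste(miss, collapse = ", "))
  meta <- metadata[match(rownames(M), metadata$sample_id),
                   c("sample_id", "class", "pair_id")]
  ProteinTable(M, colnames(M), meta)
}

#' Write a protein abundance-ratio table
#'
#' @param table a \linkS4class{ProteinTable}.
#' @param path output TSV path (samples as rows).
#' @return \code{path}, invisibly.
#' @export
writeProteinTable <- function(table, path) {
  M <- ratios(table)
  out <- data.frame(sample_id = rownames(M), check.names = FALSE)
  out[colnames(M)] <- as.data.frame(M, check.names = FALSE)
  utils::write.table(format(out, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a structured results record
#'
#' Serializes pooled metrics, per-session metrics, feature ranking, the full
#' run configuration and all session seeds to JSON, so any run can be
#' reproduced bit-for-bit from its own results file.
#'
#' @param results list as produced by \code{\link{ftirPipeline}} or
#'   \code{\link{msPipeline}}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeResults <- function(results, path) {
  if (is.null(results$config))
    stop("serialization error: results must carry the full run config")
  ser <- results
  if (is(ser$pooled, "PooledMetrics"))
    ser$pooled <- list(estimates = pooledEstimates(ser$pooled),
                       n_sessions = ser$pooled@nSessions,
                       pooling = ser$pooled@pooling)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' Read back a results record written by \code{\link{writeResults}}
#'
#' @param path JSON path.
#' @return the deserialized list (pooled metrics as a plain list).
#' @export
readResults <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}
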
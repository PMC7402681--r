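#' Write LFP traces as delimited text with a metadata sidecar
#'
#' Each trace becomes one column of a tab-separated samples file; a sidecar
#' table (`<path>.meta.tsv`) records one row per trace (seed, g, nu0, rate,
#' duration).
#'
#' @param traces List of `lfp_trace` objects of equal length and rate.
#' @param path Output path for the samples matrix.
#' @return The samples path, invisibly.
#' @export
write_lfp_traces <- function(traces, path) {
  lens <- vapply(traces, function(tr) length(tr$samples), 0L)
  if (length(unique(lens)) != 1) stop("traces must have equal length")
  mat <- vapply(traces, function(tr) tr$samples, numeric(lens[1]))
  colnames(mat) <- sprintf("trace_%03d", seq_along(traces))
  utils::write.table(mat, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- data.frame(
    trace = colnames(mat),
    seed = vapply(traces, function(tr) as.numeric(tr$meta$seed %||% NA), 0),
    g = vapply(traces, function(tr) as.numeric(tr$meta$g %||% NA), 0),
    nu0 = vapply(traces, function(tr) as.numeric(tr$meta$nu0 %||% NA), 0),
    rate = vapply(traces, function(tr) tr$rate, 0),
    duration = vapply(traces, function(tr) tr$duration, 0)
  )
  utils::write.table(meta, paste0(path, ".meta.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_lfp_traces
#' @export
read_lfp_traces <- function(path) {
  mat <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE))
  meta <- utils::read.table(paste0(path, ".meta.tsv"), sep = "\t",
                            header = TRUE)
  lapply(seq_len(ncol(mat)), function(i) {
    lfp_trace(mat[, i], meta$rate[i],
              meta = list(seed = meta$seed[i], g = meta$g[i],
                          nu0 = meta$nu0[i]))
  })
}

#' Write spikes as two-column delimited text
#'
#' @param sim A `sim_output`.
#' @param path Output path (`neuron_id`, `time_s`; tab-separated).
#' @export
write_spikes <- function(sim, path) {
  utils::write.table(
    data.frame(neuron_id = sim$spikes$neuron, time_s = sim$spikes$time),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a parcel-by-time matrix from delimited text
#'
#' Rows are time points, columns are parcels/units, with a header row of
#' labels (the layout used for parcellated BOLD time series).
#'
#' @param path Input path (tab- or comma-separated; inferred).
#' @return Numeric matrix with parcel labels as column names.
#' @export
read_timeseries_matrix <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else "\t"
  mat <- as.matrix(utils::read.table(path, sep = sep, header = TRUE,
                                     check.names = FALSE))
  storage.mode(mat) <- "double"
  mat
}

`%||%` <- function(a, b) if (is.null(a)) b else a
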
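#' Read and write pipeline file formats
#'
#' Plain-text interchange formats used by the pipeline: tracking CSV
#' (`t_s,x_cm,y_cm`), photometry CSV (`t_s,f465,f405,led_state`), wide
#' sweep CSV (`t_s` plus one column per sweep, labeled in the header),
#' counts TSV (genes x samples) with a samples TSV, events CSV, and JSON
#' truth sidecars. All writers are deterministic (fixed column order, no
#' timestamps) so reruns under a fixed seed are byte-identical.
#'
#' @param trace,path,events,sweeps,counts,samples,x Objects/paths as named.
#' @name socphys_io
NULL

fmt_num <- function(x, digits = 10) {
  # deterministic, locale-independent numeric formatting
  formatC(x, digits = digits, format = "g")
}

#' @rdname socphys_io
#' @export
write_tracking_csv <- function(trace, path) {
  df <- data.frame(t_s = fmt_num(trace$t_s), x_cm = fmt_num(trace$x_cm),
                   y_cm = fmt_num(trace$y_cm))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname socphys_io
#' @export
read_tracking_csv <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("t_s", "x_cm", "y_cm") %in% names(df)))
  df
}

#' @rdname socphys_io
#' @export
write_events_csv <- function(events, path) {
  df <- data.frame(stimulus = events$stimulus,
                   t_entry = fmt_num(events$t_entry),
                   t_exit = fmt_num(events$t_exit),
                   included = events$included,
                   reason = events$reason)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname socphys_io
#' @export
read_events_csv <- function(path) read.csv(path)

#' @rdname socphys_io
#' @export
write_sweeps_csv <- function(sweeps, path) {
  df <- data.frame(t_s = sweeps$t)
  for (j in seq_along(sweeps$sweep_labels)) {
    df[[paste0("sweep_", sweeps$sweep_labels[j])]] <- sweeps$traces[, j]
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname socphys_io
#' @export
write_counts_tsv <- function(counts, samples, path, samples_path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(samples, samples_path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname socphys_io
#' @export
read_counts_tsv <- function(path, samples_path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  storage.mode(counts) <- "integer"
  samples <- read.table(samples_path, sep = "\t", header = TRUE)
  list(counts = counts, samples = samples)
}

#' @rdname socphys_io
#' @export
write_truth_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
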
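# Plain-text I/O: tab-delimited matrices with a one-line header naming rows,
# JSON for structured reports.  Everything the pipeline writes is re-readable
# by these functions.

#' Write a numeric matrix as TSV with row labels
#'
#' First column holds row labels (`row_label` + index, or existing rownames);
#' remaining columns the matrix, row-major.
#'
#' @param x numeric matrix.
#' @param path output file.
#' @param row_label prefix used when `x` has no rownames.
#' @return `path`, invisibly.
#' @export
write_tsv_matrix <- function(x, path, row_label = "row") {
  x <- as.matrix(x)
  labs <- rownames(x)
  if (is.null(labs)) labs <- paste0(row_label, seq_len(nrow(x)))
  df <- data.frame(labs, x, check.names = FALSE)
  colnames(df) <- c(row_label, paste0("t", seq_len(ncol(x))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a matrix written by [write_tsv_matrix()]
#'
#' @param path TSV file with a header line and a leading row-label column.
#' @return Numeric matrix with rownames from the label column.
#' @export
read_tsv_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Read a scene directory written by [write_scene()]
#'
#' @param dir directory containing `bold.tsv`, `eeg.tsv`, `truth.json`.
#' @return A list mirroring the [synth_scene()] structure.
#' @export
read_scene <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  bold <- read_tsv_matrix(file.path(dir, "bold.tsv"))
  eeg <- read_tsv_matrix(file.path(dir, "eeg.tsv"))
  states <- if (is.matrix(truth$states)) {
    lapply(seq_len(nrow(truth$states)), function(i) truth$states[i, ])
  } else truth$states
  list(states = states, weights = truth$weights,
       bold = roi_timeseries(bold, truth$params$TR),
       eeg = eeg, fs = truth$params$fs, psi_true = truth$psi_true,
       params = truth$params, seed = truth$seed)
}
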
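#' Persist a batch as an Arrow IPC (Feather v2) file
#'
#' One record batch per file, uncompressed so readers can memory-map
#' the columns; the SAM header travels in the file-level metadata under
#' the key `"sam_header"` (header lines joined by newlines, verbatim).
#'
#' @param batch a [read_batch].
#' @param header a [sam_header], or `NULL`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_batch_ipc <- function(batch, header, path) {
  df <- as.data.frame(unclass(batch), stringsAsFactors = FALSE)
  tab <- arrow::arrow_table(df)
  if (!is.null(header))
    tab$metadata$sam_header <- paste(header$raw_lines, collapse = "\n")
  arrow::write_feather(tab, path, compression = "uncompressed")
  invisible(path)
}

#' Read a batch back from an Arrow IPC file
#'
#' @param path file written by [write_batch_ipc].
#' @return A list with `batch` ([read_batch]) and `header`
#'   ([sam_header], or `NULL` when the file carries no header metadata).
#' @export
read_batch_ipc <- function(path) {
  tab <- arrow::read_feather(path, as_data_frame = FALSE, mmap = TRUE)
  hdr <- tab$metadata$sam_header
  header <- if (!is.null(hdr)) {
    lines <- if (nzchar(hdr)) strsplit(hdr, "\n", fixed = TRUE)[[1L]]
             else character()
    sam_header(lines)
  } else NULL
  list(batch = as_read_batch(as.data.frame(tab)), header = header)
}
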
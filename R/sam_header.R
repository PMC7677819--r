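#' SAM headers
#'
#' A `sam_header` keeps the header text lines verbatim (so that
#' serialisation is byte-identical to the input) together with the parsed
#' reference dictionary from the `@SQ` lines, which fixes the chromosome
#' order used for partitioning and export.
#'
#' @param raw_lines character vector of header lines, each starting `@`.
#' @return An object of class `sam_header` with fields `raw_lines`,
#'   `references` (named integer vector, name -> length in bases) and
#'   `sort_order` (one of `unknown`, `unsorted`, `queryname`,
#'   `coordinate`).
#' @export
sam_header <- function(raw_lines = character()) {
  if (length(raw_lines) && !all(startsWith(raw_lines, "@")))
    stop("header lines must start with '@'")
  refs <- integer()
  sort_order <- "unknown"
  for (ln in raw_lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (fields[1L] == "@SQ") {
      sn <- sub("^SN:", "", grep("^SN:", fields, value = TRUE)[1L])
      lnv <- sub("^LN:", "", grep("^LN:", fields, value = TRUE)[1L])
      if (is.na(sn) || is.na(lnv))
        stop("@SQ line lacks SN or LN: ", ln)
      len <- suppressWarnings(as.integer(lnv))
      if (is.na(len) || len <= 0L)
        stop("@SQ LN must be a positive integer: ", ln)
      if (sn %in% names(refs))
        stop("duplicate reference name in header: ", sn)
      refs[sn] <- len
    } else if (fields[1L] == "@HD") {
      so <- sub("^SO:", "", grep("^SO:", fields, value = TRUE)[1L])
      if (!is.na(so) && so %in% c("unknown", "unsorted", "queryname",
                                  "coordinate"))
        sort_order <- so
    }
  }
  structure(list(raw_lines = raw_lines, references = refs,
                 sort_order = sort_order),
            class = "sam_header")
}

#' Build a minimal header from a reference dictionary
#'
#' @param references named integer vector, reference name -> length.
#' @param sort_order value for the `@HD SO:` field.
#' @return A `sam_header` with one `@HD` line and one `@SQ` line per
#'   reference.
#' @export
make_header <- function(references, sort_order = "unknown") {
  lines <- c(paste0("@HD\tVN:1.6\tSO:", sort_order),
             sprintf("@SQ\tSN:%s\tLN:%d", names(references),
                     as.integer(references)))
  sam_header(lines)
}

#' @export
print.sam_header <- function(x, ...) {
  cat("<sam_header> ", length(x$raw_lines), " lines, ",
      length(x$references), " references, sort_order=", x$sort_order,
      "\n", sep = "")
  invisible(x)
}

#' Chromosome processing order implied by a header
#'
#' Reference names in `@SQ` order, followed by the reserved unmapped
#' partition key `"*"`.
#'
#' @param header a `sam_header`.
#' @return Character vector of partition keys.
#' @export
chrom_order <- function(header) c(names(header$references), "*")
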
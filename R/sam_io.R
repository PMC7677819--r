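#' Read a SAM text file into a header and a columnar batch
#'
#' Parses plain-text SAM (v1.6 layout): zero or more `@` header lines
#' captured verbatim, then alignment lines with at least 11 tab-separated
#' fields.  Fields 1-11 map to the eleven mandatory columns; fields 12
#' onward are tab-joined verbatim into the `tags` column (empty string
#' when absent), which is what makes export byte-identical to the input.
#'
#' @param source path to a SAM file, or a character vector of lines.
#' @return A list with elements `header` (a [sam_header]) and `batch`
#'   (a [read_batch]).
#' @export
read_sam <- function(source) {
  lines <- if (length(source) == 1L && !grepl("\t", source) &&
               file.exists(source)) readLines(source) else source
  is_hdr <- startsWith(lines, "@")
  if (any(is_hdr) && !all(which(is_hdr) == seq_len(sum(is_hdr))))
    stop("header lines must precede all alignment lines")
  header <- sam_header(lines[is_hdr])
  aln <- lines[!is_hdr]
  aln <- aln[nzchar(aln)]
  if (!length(aln)) return(list(header = header, batch = empty_read_batch()))
  parts <- strsplit(aln, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 11L)) {
    i <- which(nf < 11L)[1L]
    stop("SAM line ", sum(is_hdr) + i, " has ", nf[i],
         " fields; 11 required")
  }
  field <- function(k) vapply(parts, `[[`, character(1L), k)
  int_field <- function(k, name) {
    raw <- field(k)
    v <- suppressWarnings(as.integer(raw))
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stop("SAM line ", sum(is_hdr) + i, ": field ", name,
           " is not an integer: '", raw[i], "'")
    }
    v
  }
  tags <- vapply(parts, function(p) {
    if (length(p) > 11L) paste(p[12:length(p)], collapse = "\t") else ""
  }, character(1L))
  batch <- read_batch(
    qname = field(1L), flag = int_field(2L, "FLAG"), rname = field(3L),
    pos = int_field(4L, "POS"), mapq = int_field(5L, "MAPQ"),
    cigar = field(6L), rnext = field(7L), pnext = int_field(8L, "PNEXT"),
    tlen = int_field(9L, "TLEN"), seq = field(10L), qual = field(11L),
    tags = tags)
  list(header = header, batch = batch)
}

#' Serialise a batch back to SAM text lines
#'
#' @param batch a [read_batch].
#' @return Character vector of alignment lines (no header).
#' @export
format_sam_lines <- function(batch) {
  if (!nrow(batch)) return(character())
  core <- paste(batch$qname, batch$flag, batch$rname, batch$pos,
                batch$mapq, batch$cigar, batch$rnext, batch$pnext,
                batch$tlen, batch$seq, batch$qual, sep = "\t")
  has_tags <- nzchar(batch$tags)
  core[has_tags] <- paste(core[has_tags], batch$tags[has_tags], sep = "\t")
  core
}

#' Write header and batch as a SAM text file
#'
#' Inverse of [read_sam]: `read_sam(write_sam(h, b))` reproduces the
#' header lines and alignment lines byte-identically.
#'
#' @param header a [sam_header].
#' @param batch a [read_batch].
#' @param sink output file path, or a connection.
#' @return Invisibly, the number of alignment rows written.
#' @export
write_sam <- function(header, batch, sink) {
  lines <- c(header$raw_lines, format_sam_lines(batch))
  writeLines(lines, sink)
  invisible(nrow(batch))
}

#' Read a BED interval file
#'
#' Accepts BED3+ (0-based, half-open).  Lines starting `track`,
#' `browser` or `#` are skipped.  Intervals are sorted by
#' (chrom, start) and overlapping or adjacent intervals on the same
#' chromosome are merged, so downstream membership tests see a canonical
#' disjoint set.
#'
#' @param source path to a BED file, or a character vector of lines.
#' @return An `interval_set`: a data frame with columns `chrom`,
#'   `start` (0-based inclusive), `end` (0-based exclusive).
#' @export
read_bed <- function(source) {
  lines <- if (length(source) == 1L && !grepl("\t", source) &&
               file.exists(source)) readLines(source) else source
  keep <- !(startsWith(lines, "track") | startsWith(lines, "browser") |
              startsWith(lines, "#")) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) return(interval_set())
  recs <- lapply(idx, function(i) {
    p <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(p) < 3L)
      stop("BED line ", i, " has fewer than 3 columns")
    s <- suppressWarnings(as.integer(p[2L]))
    e <- suppressWarnings(as.integer(p[3L]))
    if (is.na(s) || is.na(e))
      stop("BED line ", i, ": non-integer coordinate")
    if (e <= s)
      stop("BED line ", i, ": end (", e, ") must exceed start (", s, ")")
    if (s < 0L)
      stop("BED line ", i, ": negative start")
    list(chrom = p[1L], start = s, end = e)
  })
  df <- data.frame(chrom = vapply(recs, `[[`, character(1L), "chrom"),
                   start = vapply(recs, `[[`, integer(1L), "start"),
                   end = vapply(recs, `[[`, integer(1L), "end"),
                   stringsAsFactors = FALSE)
  interval_set(df)
}

#' Construct a canonical interval set
#'
#' Sorts intervals by (chrom, start) and merges overlapping and adjacent
#' intervals per chromosome (via [IRanges::reduce]).
#'
#' @param df data frame with columns `chrom`, `start`, `end` (BED
#'   coordinates: 0-based, half-open).
#' @return A data frame of class `interval_set` in canonical form.
#' @export
interval_set <- function(df = NULL) {
  if (is.null(df) || !nrow(df)) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
    class(out) <- c("interval_set", "data.frame")
    return(out)
  }
  merged <- lapply(split(df, df$chrom), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(start = d$start + 1L,
                                           end = d$end),
                          min.gapwidth = 1L)
    data.frame(chrom = d$chrom[1L],
               start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged[order(names(merged))])
  rownames(out) <- NULL
  class(out) <- c("interval_set", "data.frame")
  out
}
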
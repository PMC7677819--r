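#' QUAL + INDEX delta column pair
#'
#' The output of the interval-filtered quality-update stage for one
#' chunk: a replacement quality string per surviving row, and an INDEX
#' column mapping each surviving row back to its 0-based source row
#' among the chunk's owned rows.  Downstream stages use INDEX as an
#' alternative to re-evaluating intervals: gathering source columns at
#' INDEX yields exactly the reads inside the intervals.
#'
#' @param qual character vector of replacement Phred+33 strings.
#' @param index integer vector of 0-based owned-row indices, strictly
#'   increasing, same length as `qual`.
#' @return A `qual_index_delta`.
#' @export
qual_index_delta <- function(qual = character(), index = integer()) {
  qual <- as.character(qual); index <- as.integer(index)
  if (length(qual) != length(index))
    stop("qual and index columns must have equal length")
  if (length(index) > 1L && any(diff(index) <= 0L))
    stop("index column must be strictly increasing")
  if (length(index) && index[1L] < 0L)
    stop("index values must be >= 0")
  structure(list(qual = qual, index = index), class = "qual_index_delta")
}

.STAGE_COLUMNS <- list(
  markdup = c("QNAME", "FLAG", "RNAME", "POS", "CIGAR", "RNEXT"),
  bqsr = c("RNAME", "POS", "MAPQ", "CIGAR", "SEQ", "QUAL", "FLAG"),
  applybqsr = c("RNAME", "POS", "MAPQ", "CIGAR", "SEQ", "QUAL", "FLAG"),
  haplotypecaller = c("RNAME", "POS", "MAPQ", "CIGAR", "SEQ", "FLAG",
                      "QUAL", "INDEX"))

#' Per-stage field projection of a chunk
#'
#' Each pipeline stage touches only a fixed subset of the twelve SAM
#' columns; a stage view exposes exactly that subset and nothing else.
#' The duplicate-marking view reads the six key-building fields from the
#' source.  The recalibration views add the merged FLAG column produced
#' by duplicate marking (required).  The variant-calling view reads five
#' source fields, the merged FLAG, and the replacement QUAL plus INDEX
#' from the interval stage (required); its QUAL and INDEX columns have
#' one entry per surviving row while the source-backed columns cover all
#' owned rows.
#'
#' @param chunk a [sam_chunk].
#' @param stage one of `"markdup"`, `"bqsr"`, `"applybqsr"`,
#'   `"haplotypecaller"`.
#' @param flagdelta a [flag_delta] (required for every stage after
#'   duplicate marking).
#' @param qualindex a [qual_index_delta] (required for the
#'   variant-calling view).
#' @return A `stage_view`: list with `stage` and `columns` (named list
#'   of column vectors over the chunk's owned rows).
#' @export
stage_view <- function(chunk, stage = names(.STAGE_COLUMNS),
                       flagdelta = NULL, qualindex = NULL) {
  stage <- match.arg(stage)
  src <- owned_rows(chunk)
  need <- .STAGE_COLUMNS[[stage]]
  if ("FLAG" %in% need && stage != "markdup") {
    if (is.null(flagdelta))
      stop("stage '", stage, "' requires a delta from namespace 'flagdelta'")
    if (length(flagdelta$flags) != nrow(src))
      stop("flagdelta length does not match owned row count")
  }
  if (stage == "haplotypecaller" && is.null(qualindex))
    stop("stage 'haplotypecaller' requires a delta from namespace ",
         "'qualindex'")
  cols <- lapply(need, function(nm) {
    switch(nm,
           QNAME = src$qname, RNAME = src$rname, POS = src$pos,
           MAPQ = src$mapq, CIGAR = src$cigar, RNEXT = src$rnext,
           SEQ = src$seq,
           FLAG = if (stage == "markdup") src$flag else flagdelta$flags,
           QUAL = if (stage == "haplotypecaller") qualindex$qual
                  else src$qual,
           INDEX = qualindex$index)
  })
  names(cols) <- need
  structure(list(stage = stage, columns = cols), class = "stage_view")
}

#' Interval filter over a chunk's owned rows
#'
#' A row survives iff its reference span `[pos, pos + ref_len - 1]`
#' (1-based, inclusive; `ref_len` = reference bases consumed by the
#' CIGAR) overlaps any interval of its chromosome.  BED intervals
#' (0-based, half-open) are converted to 1-based inclusive before the
#' overlap test.  Rows with CIGAR `"*"` or `pos == 0` never survive.
#'
#' @param chunk a sorted [sam_chunk].
#' @param intervals an [interval_set].
#' @return Strictly increasing integer vector of 0-based owned-row
#'   indices of surviving rows.
#' @export
filter_by_intervals <- function(chunk, intervals) {
  src <- owned_rows(chunk)
  n <- nrow(src)
  if (!n) return(integer())
  iv <- intervals[intervals$chrom == chunk$chrom, , drop = FALSE]
  if (!nrow(iv)) return(integer())
  ok <- src$cigar != "*" & src$pos >= 1L
  if (!any(ok)) return(integer())
  reflen <- cigar_ref_len(src$cigar[ok])
  reads <- IRanges::IRanges(start = src$pos[ok],
                            end = src$pos[ok] + reflen - 1L)
  targets <- IRanges::IRanges(start = iv$start + 1L, end = iv$end)
  hit <- IRanges::overlapsAny(reads, targets)
  sort(which(ok)[hit]) - 1L
}

#' Apply a per-base quality transform to interval-surviving rows
#'
#' The transform is a pluggable mapping from Phred value to Phred value
#' (an externally supplied recalibration result, a constant cap, or the
#' identity); it is applied base-wise to the quality string of every
#' surviving row, preserving string lengths.  Rows whose quality is
#' `"*"` (unavailable) pass through unchanged.
#'
#' @param chunk a [sam_chunk].
#' @param index 0-based owned-row indices (from [filter_by_intervals]).
#' @param transform function mapping an integer vector of Phred values
#'   (0..93) to same-length integer Phred values; default identity.
#' @return A [qual_index_delta].
#' @export
apply_qual_transform <- function(chunk, index, transform = identity) {
  src <- owned_rows(chunk)
  index <- as.integer(index)
  if (length(index) && (min(index) < 0L || max(index) >= nrow(src)))
    stop("index out of range for chunk owned rows")
  if (!length(index)) return(qual_index_delta())
  dom <- 0:93
  img <- as.integer(transform(dom))
  if (length(img) != length(dom) || anyNA(img) ||
      any(img < 0L | img > 93L))
    stop("quality transform must map Phred 0..93 into Phred 0..93")
  old_chars <- intToUtf8(dom + 33L)
  new_chars <- intToUtf8(img + 33L)
  qual <- src$qual[index + 1L]
  live <- qual != "*"
  qual[live] <- chartr(old_chars, new_chars, qual[live])
  qual_index_delta(qual, index)
}

#' Materialise a chunk's final reads from its deltas
#'
#' Gathers the chunk's owned rows at the delta's INDEX (so only
#' interval-surviving rows appear, in source order), substituting the
#' FLAG column from the FLAG delta and the QUAL column from the
#' QUAL+INDEX delta.  With identity deltas this reproduces the source
#' rows with updated flags.
#'
#' @param chunk a [sam_chunk].
#' @param flagdelta a [flag_delta] over the owned rows, or `NULL` to
#'   keep source flags.
#' @param qualindexdelta a [qual_index_delta], or `NULL` to keep all
#'   rows and source qualities.
#' @return A [read_batch].
#' @export
resolve_reads <- function(chunk, flagdelta = NULL, qualindexdelta = NULL) {
  src <- owned_rows(chunk)
  if (!is.null(flagdelta)) {
    if (length(flagdelta$flags) != nrow(src))
      stop("flagdelta length (", length(flagdelta$flags),
           ") does not match owned rows (", nrow(src), ")")
    bad <- bitwAnd(bitwXor(flagdelta$flags, src$flag), bitwNot(0x400L)) != 0L
    if (any(bad))
      stop("flagdelta alters bits other than 0x400 at row ",
           which(bad)[1L] - 1L)
  }
  if (is.null(qualindexdelta)) {
    out <- src
    if (!is.null(flagdelta)) out$flag <- flagdelta$flags
    return(out)
  }
  idx <- qualindexdelta$index
  if (length(idx) && length(qualindexdelta$qual) != length(idx))
    stop("qualindex delta has inconsistent column lengths")
  out <- slice_rows(src, idx)
  if (!is.null(flagdelta)) out$flag <- flagdelta$flags[idx + 1L]
  live <- out$qual != "*" & qualindexdelta$qual != "*"
  if (any(live & nchar(out$qual) != nchar(qualindexdelta$qual)))
    stop("replacement quality length differs from source at some row")
  out$qual <- qualindexdelta$qual
  out
}

#' Export the pipeline result as SAM
#'
#' Walks the `"sorted"` namespace in header reference order, resolves
#' every chunk against its available deltas (`"flagdelta"`,
#' `"qualindex"`), and writes coordinate-ordered SAM -- one file, or one
#' file per chromosome plus one for the unmapped partition.  The
#' unmapped `"*"` partition is appended last; when interval filtering
#' was run (a `"qualindex"` namespace exists) unmapped reads are outside
#' every interval and are therefore not exported.
#'
#' @param store an `object_store`.
#' @param header a [sam_header].
#' @param sink output SAM path (single-file mode) or path prefix
#'   (per-chromosome mode: `<prefix>.<chrom>.sam`,
#'   `<prefix>.unmapped.sam`).
#' @param per_chrom write one file per chromosome instead of one file.
#' @return Invisibly, a list with `rows_written` and `files`.
#' @export
export_final <- function(store, header, sink, per_chrom = FALSE) {
  keys <- store_keys(store, "sorted", header = header)
  if (!length(keys)) stop("no objects in namespace 'sorted'")
  filtering <- length(store_keys(store, "qualindex")) > 0L
  chroms <- unique(vapply(keys, `[[`, character(1L), "chrom"))
  chroms <- chroms[order(match(chroms, chrom_order(header)))]
  files <- character()
  rows_written <- 0L
  single_lines <- list()
  for (chrom in chroms) {
    ck <- Filter(function(k) k$chrom == chrom, keys)
    ck <- ck[order(vapply(ck, `[[`, integer(1L), "ordinal"))]
    lines <- character()
    for (k in ck) {
      chunk <- store_get(store, k)
      fk <- object_key("flagdelta", chrom, k$ordinal)
      qk <- object_key("qualindex", chrom, k$ordinal)
      fd <- if (store_has(store, fk)) store_get(store, fk) else NULL
      qd <- if (store_has(store, qk)) store_get(store, qk)
            else if (filtering) qual_index_delta() else NULL
      out <- resolve_reads(chunk, fd, qd)
      lines <- c(lines, format_sam_lines(out))
      rows_written <- rows_written + nrow(out)
    }
    if (per_chrom) {
      fn <- paste0(sink, ".", if (chrom == "*") "unmapped" else chrom,
                   ".sam")
      writeLines(c(header$raw_lines, lines), fn)
      files <- c(files, fn)
    } else single_lines[[chrom]] <- lines
  }
  if (!per_chrom) {
    writeLines(c(header$raw_lines, unlist(single_lines, use.names = FALSE)),
               sink)
    files <- sink
  }
  invisible(list(rows_written = rows_written, files = files))
}
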
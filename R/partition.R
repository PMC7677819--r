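#' Chunks and partitions
#'
#' A partition holds one chromosome's reads as an ordered list of
#' bounded-size chunks.  A chunk owns a contiguous block of the
#' partition's rows and may additionally carry read-only *padding* rows
#' copied from its neighbours within `pad_bp` of each cut, so that
#' per-chunk duplicate marking sees complete candidate groups whose
#' unclipped ends straddle a cut.  Padding rows influence grouping and
#' scoring but are never part of a chunk's own output.
#'
#' @param batch a [read_batch] holding `n_pad_head` leading padding
#'   rows, then the owned rows, then `n_pad_tail` trailing padding rows.
#' @param chrom the partition's reference name (`"*"` for unmapped).
#' @param ordinal 0-based chunk index within its partition.
#' @param n_pad_head,n_pad_tail padding row counts at either end.
#' @param sorted whether rows are nondecreasing in `pos`.
#' @return A `sam_chunk`.
#' @export
sam_chunk <- function(batch, chrom, ordinal = 0L, n_pad_head = 0L,
                      n_pad_tail = 0L, sorted = FALSE) {
  stopifnot(is_read_batch(batch))
  if (chrom != "*" && nrow(batch) && !all(batch$rname == chrom))
    stop("chunk rows must all have rname == ", chrom)
  n_pad_head <- as.integer(n_pad_head); n_pad_tail <- as.integer(n_pad_tail)
  if (n_pad_head + n_pad_tail > nrow(batch))
    stop("padding exceeds chunk row count")
  if (sorted && nrow(batch) > 1L && is.unsorted(batch$pos))
    stop("chunk flagged sorted but pos is not nondecreasing")
  own <- seq.int(n_pad_head + 1L, length.out = nrow(batch) - n_pad_head -
                   n_pad_tail)
  span <- if (length(own) && chrom != "*")
    c(min(batch$pos[own]), max(batch$pos[own])) else c(NA_integer_,
                                                       NA_integer_)
  structure(list(batch = batch, chrom = chrom, ordinal = as.integer(ordinal),
                 n_pad_head = n_pad_head, n_pad_tail = n_pad_tail,
                 sorted = isTRUE(sorted), pos_span = span,
                 approx_bytes = approx_bytes(slice_df(batch, own))),
            class = "sam_chunk")
}

# internal row subset that keeps the read_batch class
slice_df <- function(batch, i) {
  out <- batch[i, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("read_batch", "data.frame")
  out
}

#' Rows owned by a chunk (padding removed)
#' @param chunk a [sam_chunk].
#' @return A [read_batch].
#' @export
owned_rows <- function(chunk) {
  n <- nrow(chunk$batch)
  slice_df(chunk$batch,
           seq.int(chunk$n_pad_head + 1L,
                   length.out = n - chunk$n_pad_head - chunk$n_pad_tail))
}

#' Number of rows a chunk owns
#' @param chunk a [sam_chunk].
#' @return Integer.
#' @export
n_owned <- function(chunk)
  nrow(chunk$batch) - chunk$n_pad_head - chunk$n_pad_tail

#' @export
print.sam_chunk <- function(x, ...) {
  cat("<sam_chunk> ", x$chrom, "/", x$ordinal, ": ", n_owned(x),
      " owned rows (+", x$n_pad_head, "/", x$n_pad_tail, " padding), ",
      if (x$sorted) "sorted" else "unsorted", "\n", sep = "")
  invisible(x)
}

#' A partition: one chromosome's ordered chunks
#' @param chrom reference name.
#' @param chunks list of [sam_chunk] with consecutive ordinals from 0.
#' @return A `sam_partition`.
#' @export
sam_partition <- function(chrom, chunks) {
  ords <- vapply(chunks, `[[`, integer(1L), "ordinal")
  if (length(ords) && !identical(ords, seq_along(ords) - 1L))
    stop("chunk ordinals must be consecutive from 0")
  for (ch in chunks)
    if (ch$chrom != chrom) stop("chunk chrom mismatch in partition ", chrom)
  structure(list(chrom = chrom, chunks = chunks), class = "sam_partition")
}

#' Route reads into per-chromosome partitions
#'
#' Each read goes to the partition named by its RNAME, preserving input
#' relative order; unmapped reads (RNAME `"*"`) go to the reserved `"*"`
#' partition, which bypasses sorting and duplicate marking and is
#' re-appended at export.
#'
#' @param header a [sam_header]; every RNAME must be `"*"` or a
#'   reference the header declares.
#' @param batch a [read_batch].
#' @return Named list of [read_batch], keyed by chromosome in header
#'   order (then `"*"`); only non-empty partitions are returned.
#' @export
partition_by_chrom <- function(header, batch) {
  levels <- chrom_order(header)
  bad <- which(!(batch$rname %in% levels))
  if (length(bad))
    stop("rname '", batch$rname[bad[1L]], "' at row ", bad[1L] - 1L,
         " is not declared in the header")
  f <- factor(batch$rname, levels = levels)
  idx <- split(seq_len(nrow(batch)), f, drop = TRUE)
  lapply(idx, function(i) slice_df(batch, i))
}

#' Split a sorted partition into bounded-size chunks
#'
#' Cut points fall only between rows with different `pos` values, so a
#' position group is never torn apart.  Every output chunk's owned rows
#' stay within `max_bytes` (estimated via [approx_bytes]) unless a
#' single position group alone exceeds the bound, in which case that
#' group forms one oversized chunk and a warning is emitted.  Each chunk
#' carries padding rows copied from the neighbouring rows whose `pos`
#' lies within `pad_bp` of the cut.
#'
#' @param partition a single-chunk, coordinate-sorted [sam_partition].
#' @param max_bytes chunk size bound in bytes (default 2 GiB).
#' @param pad_bp boundary padding window in base pairs (default 1000).
#' @return A (possibly multi-chunk) [sam_partition]; concatenating the
#'   owned rows of the output chunks reproduces the input batch exactly.
#' @export
split_partition <- function(partition, max_bytes = 2^31, pad_bp = 1000L) {
  stopifnot(inherits(partition, "sam_partition"))
  if (length(partition$chunks) != 1L)
    stop("split_partition expects a single-chunk partition")
  chunk <- partition$chunks[[1L]]
  batch <- owned_rows(chunk)
  n <- nrow(batch)
  if (partition$chrom == "*" || n == 0L ||
      approx_bytes(batch) <= max_bytes) {
    return(sam_partition(partition$chrom,
                         list(sam_chunk(batch, partition$chrom, 0L,
                                        sorted = chunk$sorted ||
                                          partition$chrom == "*"))))
  }
  if (!chunk$sorted || is.unsorted(batch$pos))
    stop("split_partition requires a coordinate-sorted partition")
  # per-row byte estimate mirroring approx_bytes (per-batch constant spread
  # over rows is negligible and irrelevant for cut placement determinism)
  row_bytes <- rep(4 * length(.INT_COLUMNS) + 4 * length(.CHR_COLUMNS), n)
  for (col in .CHR_COLUMNS)
    row_bytes <- row_bytes + nchar(batch[[col]], type = "bytes")
  # position groups: runs of equal pos
  grp <- cumsum(c(TRUE, batch$pos[-1L] != batch$pos[-n]))
  grp_bytes <- as.numeric(tapply(row_bytes, grp, sum))
  grp_end <- cumsum(tabulate(grp))
  grp_start <- c(1L, grp_end[-length(grp_end)] + 1L)
  cuts <- integer()          # last row index of each finished chunk
  acc <- 0
  chunk_start_grp <- 1L
  for (g in seq_along(grp_bytes)) {
    if (g > chunk_start_grp && acc + grp_bytes[g] > max_bytes) {
      cuts <- c(cuts, grp_end[g - 1L])
      chunk_start_grp <- g
      acc <- 0
    }
    acc <- acc + grp_bytes[g]
    if (grp_bytes[g] > max_bytes && g == chunk_start_grp)
      warning("position group at pos ", batch$pos[grp_start[g]],
              " alone exceeds max_bytes; emitting oversized chunk")
  }
  bounds <- c(0L, cuts, n)   # owned row ranges: (bounds[i]+1) .. bounds[i+1]
  chunks <- vector("list", length(bounds) - 1L)
  for (k in seq_len(length(bounds) - 1L)) {
    lo <- bounds[k] + 1L
    hi <- bounds[k + 1L]
    # padding: neighbour rows within pad_bp of the cut positions
    head_from <- lo
    while (head_from > 1L && batch$pos[head_from - 1L] >=
           batch$pos[lo] - pad_bp) head_from <- head_from - 1L
    tail_to <- hi
    while (tail_to < n && batch$pos[tail_to + 1L] <=
           batch$pos[hi] + pad_bp) tail_to <- tail_to + 1L
    chunks[[k]] <- sam_chunk(slice_df(batch, head_from:tail_to),
                             partition$chrom, ordinal = k - 1L,
                             n_pad_head = lo - head_from,
                             n_pad_tail = tail_to - hi, sorted = TRUE)
  }
  sam_partition(partition$chrom, chunks)
}
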
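#' Coordinate-sort one partition
#'
#' Stable sort by leftmost mapping position only: rows with equal `pos`
#' keep their input relative order, and the sort key deliberately
#' excludes qname/flag so the result is the field-standard coordinate
#' order within a chromosome.  Reads with `pos == 0` inside a named
#' chromosome sort first (they precede `pos >= 1` numerically).  The
#' unmapped `"*"` partition passes through untouched.
#'
#' @param partition a [sam_partition] (any chunking; rows in any order).
#' @return A single-chunk, sorted [sam_partition].
#' @export
sort_partition <- function(partition) {
  stopifnot(inherits(partition, "sam_partition"))
  batch <- concat_batches(lapply(partition$chunks, owned_rows))
  if (partition$chrom != "*" && nrow(batch) &&
      length(unique(batch$rname)) > 1L)
    stop("mixed rname values in partition ", partition$chrom, ": ",
         paste(unique(batch$rname), collapse = ", "))
  if (partition$chrom != "*" && nrow(batch) > 1L) {
    o <- order(batch$pos, method = "radix")     # radix order is stable
    batch <- slice_df(batch, o)
  }
  sam_partition(partition$chrom,
                list(sam_chunk(batch, partition$chrom, 0L, sorted = TRUE)))
}

.chrom_lapply <- function(chroms, workers, fn) {
  if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(chroms, fn, mc.cores = workers)
  } else lapply(chroms, fn)
}

#' Sort every partition in the store, chromosome-parallel
#'
#' Reads each chromosome's objects from `in_namespace`, sorts the whole
#' chromosome, splits it into bounded chunks, and seals one object per
#' (chromosome, ordinal) in `out_namespace`.  Output content is
#' independent of the worker count and of completion order; the input
#' namespace generation is dropped afterwards unless kept by request.
#'
#' @param store an `object_store`.
#' @param header a [sam_header] (fixes chromosome order).
#' @param in_namespace,out_namespace store namespaces (defaults
#'   `"aligned"` -> `"sorted"`).
#' @param workers number of parallel workers.
#' @param max_bytes,pad_bp chunking parameters, see [split_partition].
#' @param drop_input delete the input namespace generation on success.
#' @return Named integer vector of per-chromosome row counts.
#' @export
sort_all <- function(store, header, in_namespace = "aligned",
                     out_namespace = "sorted", workers = 1L,
                     max_bytes = 2^31, pad_bp = 1000L,
                     drop_input = TRUE) {
  keys <- store_keys(store, in_namespace, header = header)
  if (!length(keys)) return(stats::setNames(integer(), character()))
  chroms <- unique(vapply(keys, `[[`, character(1L), "chrom"))
  chroms <- chroms[order(match(chroms, chrom_order(header)))]
  res <- .chrom_lapply(chroms, workers, function(chrom) {
    ck <- Filter(function(k) k$chrom == chrom, keys)
    ck <- ck[order(vapply(ck, `[[`, integer(1L), "ordinal"))]
    chunks <- lapply(seq_along(ck), function(i) {
      p <- store_get(store, ck[[i]])
      if (inherits(p, "sam_chunk")) p
      else sam_chunk(p, chrom, i - 1L)
    })
    part <- sort_partition(sam_partition(chrom, chunks))
    part <- split_partition(part, max_bytes = max_bytes, pad_bp = pad_bp)
    for (ch in part$chunks)
      store_put(store, object_key(out_namespace, chrom, ch$ordinal), ch)
    sum(vapply(part$chunks, n_owned, integer(1L)))
  })
  if (drop_input)
    for (k in keys) store_delete(store, k)
  stats::setNames(as.integer(unlist(res)), chroms)
}
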
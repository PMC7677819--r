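#' Shared object store of sealed, immutable record batches
#'
#' Pipeline stages never hand data to each other directly: every
#' intermediate -- a chunk of reads, a FLAG delta, a QUAL+INDEX delta --
#' is written once into a shared pool as a named, sealed, immutable
#' object, and downstream stages (possibly different OS processes) read
#' it from there.  The pool is a directory of uncompressed Arrow IPC
#' (Feather v2) files, one per object, read back memory-mapped so
#' retrieval does not re-parse SAM text and does not copy column
#' contents per consumer.  Sealing is atomic: the payload is written to
#' a temporary file and renamed into place, and a JSON manifest entry is
#' written only after the payload is complete, so a concurrent reader
#' either sees a sealed object or no object at all.
#'
#' @param dir directory backing the store (created if absent).
#' @param capacity_bytes optional hard capacity; a put that would exceed
#'   it is an error (the working set is assumed to fit in memory).
#' @return An `object_store` handle.
#' @export
store_open <- function(dir, capacity_bytes = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  structure(list(dir = normalizePath(dir), capacity_bytes = capacity_bytes),
            class = "object_store")
}

#' Object keys
#'
#' @param namespace stage namespace, e.g. `"aligned"`, `"sorted"`,
#'   `"flagdelta"`, `"qualindex"`.
#' @param chrom chromosome / partition name (`"*"` for unmapped).
#' @param ordinal 0-based chunk index within the partition.
#' @return An `object_key`.
#' @export
object_key <- function(namespace, chrom, ordinal = 0L) {
  structure(list(namespace = namespace, chrom = chrom,
                 ordinal = as.integer(ordinal)),
            class = "object_key")
}

#' Rendered name of an object key
#' @param key an [object_key].
#' @return `"{namespace}/{chrom}/{ordinal}"`.
#' @export
render_key <- function(key) {
  paste(key$namespace, key$chrom, key$ordinal, sep = "/")
}

# '*' is not filesystem-friendly; encode it.
.key_fs <- function(key) {
  chrom <- if (key$chrom == "*") "__unmapped__" else key$chrom
  file.path(key$namespace, chrom, paste0(key$ordinal))
}

.payload_path <- function(store, key)
  file.path(store$dir, paste0(.key_fs(key), ".arrow"))
.entry_path <- function(store, key)
  file.path(store$dir, paste0(.key_fs(key), ".json"))

# serialize payload (data frame part + metadata list) to one IPC file
.payload_parts <- function(payload) {
  if (inherits(payload, "sam_chunk")) {
    list(df = as.data.frame(unclass(payload$batch),
                            stringsAsFactors = FALSE),
         meta = list(type = "chunk", chrom = payload$chrom,
                     ordinal = payload$ordinal,
                     n_pad_head = payload$n_pad_head,
                     n_pad_tail = payload$n_pad_tail,
                     sorted = payload$sorted,
                     pos_span = payload$pos_span))
  } else if (inherits(payload, "flag_delta")) {
    list(df = data.frame(flags = payload$flags),
         meta = list(type = "flagdelta"))
  } else if (inherits(payload, "qual_index_delta")) {
    list(df = data.frame(qual = payload$qual, index = payload$index,
                         stringsAsFactors = FALSE),
         meta = list(type = "qualindex"))
  } else if (is_read_batch(payload)) {
    list(df = as.data.frame(unclass(payload), stringsAsFactors = FALSE),
         meta = list(type = "read_batch"))
  } else if (is.data.frame(payload)) {
    list(df = payload, meta = list(type = "data.frame"))
  } else stop("unsupported payload type: ", paste(class(payload),
                                                  collapse = "/"))
}

.payload_restore <- function(df, meta) {
  switch(meta$type,
         chunk = sam_chunk(as_read_batch(df), chrom = meta$chrom,
                           ordinal = meta$ordinal,
                           n_pad_head = meta$n_pad_head,
                           n_pad_tail = meta$n_pad_tail,
                           sorted = meta$sorted),
         flagdelta = flag_delta(df$flags),
         qualindex = qual_index_delta(df$qual, df$index),
         read_batch = as_read_batch(df),
         df)
}

#' Put and seal an object
#'
#' @param store an `object_store`.
#' @param key an [object_key]; must not already be present.
#' @param payload a [read_batch], [sam_chunk], [flag_delta],
#'   [qual_index_delta] or plain data frame.
#' @return Invisibly, a list describing the stored object (key,
#'   byte_size, sealed).
#' @export
store_put <- function(store, key, payload) {
  ep <- .entry_path(store, key)
  pp <- .payload_path(store, key)
  if (file.exists(ep) || file.exists(pp))
    stop("object already present in store: ", render_key(key))
  parts <- .payload_parts(payload)
  dir.create(dirname(pp), recursive = TRUE, showWarnings = FALSE)
  tab <- arrow::arrow_table(parts$df)
  tab$metadata$colsam_meta <- jsonlite::toJSON(parts$meta, auto_unbox = TRUE,
                                               null = "null")
  tmp <- paste0(pp, ".tmp.", Sys.getpid())
  arrow::write_feather(tab, tmp, compression = "uncompressed")
  byte_size <- file.size(tmp)
  if (!is.null(store$capacity_bytes) &&
      store_size(store) + byte_size > store$capacity_bytes) {
    unlink(tmp)
    stop("object store capacity exceeded by ", render_key(key))
  }
  file.rename(tmp, pp)
  entry <- list(key = render_key(key), file = basename(pp),
                byte_size = byte_size, sealed = TRUE,
                payload_type = parts$meta$type)
  writeLines(jsonlite::toJSON(entry, auto_unbox = TRUE), ep)
  invisible(entry)
}

.read_entry <- function(store, key) {
  ep <- .entry_path(store, key)
  if (!file.exists(ep)) {
    if (file.exists(.payload_path(store, key)) ||
        length(Sys.glob(paste0(.payload_path(store, key), ".tmp.*"))))
      stop("object exists but is not sealed: ", render_key(key))
    stop("no such object in store: ", render_key(key))
  }
  jsonlite::fromJSON(readLines(ep, warn = FALSE))
}

#' Get a sealed object's payload
#'
#' The payload file is opened memory-mapped; repeated gets do not change
#' store accounting and mutating the returned R object never alters what
#' a later get returns.
#'
#' @inheritParams store_put
#' @return The payload as stored.
#' @export
store_get <- function(store, key) {
  entry <- .read_entry(store, key)
  if (!isTRUE(entry$sealed))
    stop("object is not sealed: ", render_key(key))
  tab <- arrow::read_feather(.payload_path(store, key),
                             as_data_frame = FALSE, mmap = TRUE)
  meta <- jsonlite::fromJSON(tab$metadata$colsam_meta)
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  .payload_restore(df, meta)
}

#' Does the store hold this key?
#' @inheritParams store_put
#' @return Logical.
#' @export
store_has <- function(store, key) file.exists(.entry_path(store, key))

#' Delete an object
#' @inheritParams store_put
#' @return Invisibly `TRUE`.
#' @export
store_delete <- function(store, key) {
  ep <- .entry_path(store, key)
  if (!file.exists(ep))
    stop("cannot delete missing object: ", render_key(key))
  unlink(ep)
  unlink(.payload_path(store, key))
  invisible(TRUE)
}

#' Drop a whole namespace generation
#' @param store an `object_store`.
#' @param namespace namespace to remove entirely.
#' @return Invisibly the number of objects removed.
#' @export
store_drop_namespace <- function(store, namespace) {
  keys <- store_keys(store, namespace)
  for (k in keys) store_delete(store, k)
  invisible(length(keys))
}

.decode_chrom <- function(x) ifelse(x == "__unmapped__", "*", x)

#' List keys in the store
#'
#' @param store an `object_store`.
#' @param namespace optional namespace filter.
#' @param header optional [sam_header]; when given, keys are ordered by
#'   (chromosome order in the header, ordinal), otherwise by
#'   (chromosome name, ordinal).
#' @return List of [object_key] objects.
#' @export
store_keys <- function(store, namespace = NULL, header = NULL) {
  entries <- list.files(store$dir, pattern = "\\.json$", recursive = TRUE)
  if (!length(entries)) return(list())
  parts <- strsplit(sub("\\.json$", "", entries), "/", fixed = TRUE)
  keep <- lengths(parts) == 3L
  parts <- parts[keep]
  if (!is.null(namespace))
    parts <- parts[vapply(parts, `[[`, character(1L), 1L) == namespace]
  if (!length(parts)) return(list())
  ns <- vapply(parts, `[[`, character(1L), 1L)
  chrom <- .decode_chrom(vapply(parts, `[[`, character(1L), 2L))
  ord <- as.integer(vapply(parts, `[[`, character(1L), 3L))
  chrom_rank <- if (!is.null(header)) {
    match(chrom, chrom_order(header))
  } else rank(chrom, ties.method = "min")
  o <- order(ns, chrom_rank, chrom, ord)
  lapply(o, function(i) object_key(ns[i], chrom[i], ord[i]))
}

#' Total bytes of sealed payloads in the store
#' @param store an `object_store`.
#' @return Total byte size (double).
#' @export
store_size <- function(store) {
  entries <- list.files(store$dir, pattern = "\\.json$", recursive = TRUE,
                        full.names = TRUE)
  if (!length(entries)) return(0)
  sum(vapply(entries, function(f)
    as.numeric(jsonlite::fromJSON(readLines(f, warn = FALSE))$byte_size),
    numeric(1L)))
}

#' Store inventory
#' @param store an `object_store`.
#' @param header optional [sam_header] for ordering.
#' @return Data frame with key, payload_type and byte_size per object.
#' @export
store_inventory <- function(store, header = NULL) {
  keys <- store_keys(store, header = header)
  if (!length(keys))
    return(data.frame(key = character(), payload_type = character(),
                      byte_size = numeric(), stringsAsFactors = FALSE))
  entries <- lapply(keys, function(k) .read_entry(store, k))
  data.frame(key = vapply(entries, `[[`, character(1L), "key"),
             payload_type = vapply(entries, `[[`, character(1L),
                                   "payload_type"),
             byte_size = vapply(entries, function(e)
               as.numeric(e$byte_size), numeric(1L)),
             stringsAsFactors = FALSE)
}
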
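#' Run the full pre-processing pipeline
#'
#' Orchestrates ingest -> sort -> chunk -> duplicate marking ->
#' interval filter / quality transform -> export.  All inter-stage data
#' passes through the shared object store only; no intermediate SAM
#' files are written unless `debug_dump` is set.  For a fixed (input,
#' config, seed) the exported SAM is byte-identical for any worker
#' count.
#'
#' @param config a list (or YAML path readable by [read_config]) with:
#'   \describe{
#'     \item{input}{path to a SAM file, \emph{or}}
#'     \item{sim}{a list of [simulate_reads] arguments;}
#'     \item{out}{output SAM path (required);}
#'     \item{bed}{optional BED path -- enables interval filtering;}
#'     \item{workers}{parallel workers (default 1);}
#'     \item{max_bytes}{chunk bound in bytes (default 2 GiB);}
#'     \item{pad_bp}{chunk boundary padding (default 1000);}
#'     \item{scoring}{duplicate scoring strategy;}
#'     \item{qual_transform}{function Phred -> Phred (default identity);}
#'     \item{store_dir}{object store directory (default a tempdir);}
#'     \item{per_chrom}{write per-chromosome SAM files;}
#'     \item{keep_intermediate}{keep the pre-sort namespace;}
#'     \item{debug_dump}{directory for per-stage SAM snapshots.}
#'   }
#' @return A run report: list with per-stage row counts, duplicate
#'   counts per chromosome, filtered-out count and the store inventory.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  if (is.null(config$out)) stop("config must name an output path 'out'")
  workers <- as.integer(config$workers %||% 1L)
  max_bytes <- as.numeric(config$max_bytes %||% 2^31)
  pad_bp <- as.integer(config$pad_bp %||% 1000L)
  scoring <- config$scoring %||% "sum_of_base_qualities"
  store_dir <- config$store_dir %||% tempfile("colsam_store_")
  store <- store_open(store_dir)
  t0 <- Sys.time()

  # ---- ingest ----
  if (!is.null(config$input)) {
    parsed <- read_sam(config$input)
  } else if (!is.null(config$sim)) {
    sim <- do.call(simulate_reads, config$sim)
    parsed <- list(header = sim$header, batch = sim$batch)
  } else stop("config must provide 'input' or 'sim'")
  header <- parsed$header
  n_in <- nrow(parsed$batch)
  parts <- partition_by_chrom(header, parsed$batch)
  for (chrom in names(parts))
    store_put(store, object_key("aligned", chrom, 0L),
              sam_chunk(parts[[chrom]], chrom, 0L))
  .log_stage("ingest", t0, sprintf("%d reads, %d partitions", n_in,
                                   length(parts)))
  .debug_dump(config, store, header, "aligned")

  # ---- sort + chunk ----
  t0 <- Sys.time()
  sort_counts <- sort_all(store, header, workers = workers,
                          max_bytes = max_bytes, pad_bp = pad_bp,
                          drop_input = !isTRUE(config$keep_intermediate))
  .log_stage("sort", t0, sprintf("%d chromosomes", length(sort_counts)))
  .debug_dump(config, store, header, "sorted")

  # ---- duplicate marking ----
  t0 <- Sys.time()
  dup_counts <- mark_duplicates_all(store, header, workers = workers,
                                    config = list(scoring = scoring))
  .log_stage("markdup", t0, sprintf("%d duplicates", sum(dup_counts)))

  # ---- interval filter + quality transform ----
  t0 <- Sys.time()
  n_filtered_out <- 0L
  if (!is.null(config$bed)) {
    intervals <- read_bed(config$bed)
    transform <- config$qual_transform %||% identity
    keys <- store_keys(store, "sorted", header = header)
    deltas <- .chrom_lapply(keys, workers, function(k) {
      chunk <- store_get(store, k)
      idx <- if (k$chrom == "*") integer()
             else filter_by_intervals(chunk, intervals)
      list(k = k, delta = apply_qual_transform(chunk, idx, transform),
           dropped = n_owned(chunk) - length(idx))
    })
    for (d in deltas) {
      store_put(store, object_key("qualindex", d$k$chrom, d$k$ordinal),
                d$delta)
      n_filtered_out <- n_filtered_out + d$dropped
    }
    .log_stage("filter", t0, sprintf("%d reads filtered out",
                                     n_filtered_out))
  }

  # ---- export ----
  t0 <- Sys.time()
  exp <- export_final(store, header, config$out,
                      per_chrom = isTRUE(config$per_chrom))
  .log_stage("export", t0, sprintf("%d reads -> %s", exp$rows_written,
                                   paste(exp$files, collapse = ", ")))
  if (n_in != exp$rows_written + n_filtered_out)
    stop("conservation violated: ingested ", n_in, " != exported ",
         exp$rows_written, " + filtered ", n_filtered_out)

  list(n_ingested = n_in,
       per_chrom_rows = as.list(sort_counts),
       duplicates_per_chrom = as.list(dup_counts),
       n_duplicates = sum(dup_counts),
       n_filtered_out = n_filtered_out,
       n_exported = exp$rows_written,
       files = exp$files,
       store_dir = store$dir,
       inventory = store_inventory(store, header))
}

#' Read a YAML pipeline configuration
#' @param path YAML file mirroring the [run_pipeline] config fields.
#' @return A config list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

.log_stage <- function(stage, t0, msg) {
  message(sprintf("[colsam] %-8s %6.2fs  %s", stage,
                  as.numeric(difftime(Sys.time(), t0, units = "secs")),
                  msg))
}

.debug_dump <- function(config, store, header, namespace) {
  dir <- config$debug_dump
  if (is.null(dir)) return(invisible())
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (k in store_keys(store, namespace, header = header)) {
    p <- store_get(store, k)
    b <- if (inherits(p, "sam_chunk")) owned_rows(p) else p
    fn <- file.path(dir, paste0(gsub("[/*]", "_", render_key(k)), ".sam"))
    write_sam(header, b, fn)
  }
  invisible()
}
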
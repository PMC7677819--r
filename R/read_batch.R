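#' @title Columnar read batches
#' @description A `read_batch` is the unit of storage and exchange in the
#'   columnar SAM data plane: a data frame with one column per SAM field,
#'   twelve columns in total -- the eleven mandatory SAM fields plus a
#'   `tags` column holding the tab-joined optional fields verbatim.  All
#'   columns have identical row count.  Keeping the optional fields as a
#'   single verbatim string preserves byte-exact round trips through SAM
#'   text while still giving every stage O(1) columnar access to the
#'   mandatory fields it needs.
#' @name read_batch
NULL

#' The twelve column names of a read batch, in SAM field order.
#' @export
SAM_COLUMNS <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
                 "rnext", "pnext", "tlen", "seq", "qual", "tags")

.INT_COLUMNS <- c("flag", "pos", "mapq", "pnext", "tlen")
.CHR_COLUMNS <- setdiff(SAM_COLUMNS, .INT_COLUMNS)

#' Construct a read batch
#'
#' @param qname,rname,cigar,rnext,seq,qual,tags character vectors.
#' @param flag,pos,mapq,pnext,tlen integer vectors.  `pos` and `pnext` are
#'   1-based leftmost mapping positions, 0 when unavailable.
#' @return A data frame of class `read_batch` with the twelve SAM columns.
#' @examples
#' b <- read_batch(qname = "r1", flag = 0L, rname = "chr1", pos = 100L,
#'                 mapq = 60L, cigar = "4M", rnext = "=", pnext = 100L,
#'                 tlen = 0L, seq = "ACGT", qual = "IIII", tags = "NM:i:0")
#' nrow(b)
#' @export
read_batch <- function(qname = character(), flag = integer(),
                       rname = character(), pos = integer(),
                       mapq = integer(), cigar = character(),
                       rnext = character(), pnext = integer(),
                       tlen = integer(), seq = character(),
                       qual = character(), tags = character()) {
  cols <- list(qname = as.character(qname), flag = as.integer(flag),
               rname = as.character(rname), pos = as.integer(pos),
               mapq = as.integer(mapq), cigar = as.character(cigar),
               rnext = as.character(rnext), pnext = as.integer(pnext),
               tlen = as.integer(tlen), seq = as.character(seq),
               qual = as.character(qual), tags = as.character(tags))
  n <- unique(lengths(cols))
  if (length(n) > 1L)
    stop("read_batch columns have differing lengths: ",
         paste(lengths(cols), collapse = ", "))
  df <- as.data.frame(cols, stringsAsFactors = FALSE, optional = TRUE)
  if (nrow(df) == 0L)
    df <- as.data.frame(lapply(cols, function(x) x[0]),
                        stringsAsFactors = FALSE)
  class(df) <- c("read_batch", "data.frame")
  df
}

#' Coerce a data frame to a read batch
#'
#' Checks column names and coerces column types; fails if any of the
#' twelve SAM columns is missing.
#'
#' @param df a data frame carrying the twelve SAM columns.
#' @return A `read_batch`.
#' @export
as_read_batch <- function(df) {
  missing <- setdiff(SAM_COLUMNS, names(df))
  if (length(missing))
    stop("missing read_batch columns: ", paste(missing, collapse = ", "))
  do.call(read_batch, as.list(df[SAM_COLUMNS]))
}

#' Empty read batch
#' @return A zero-row `read_batch`.
#' @export
empty_read_batch <- function() read_batch()

is_read_batch <- function(x) inherits(x, "read_batch")

# ---- CIGAR helpers ---------------------------------------------------------

.CIGAR_RE <- "^([0-9]+[MIDNSHP=X])+$"

#' Sum of CIGAR operation lengths for a set of operators
#'
#' Vectorised over `cigar`; memoised over unique strings.  Returns `NA`
#' for `"*"` (no alignment).
#'
#' @param cigar character vector of CIGAR strings.
#' @param ops character vector of single-letter CIGAR operators to sum.
#' @return Integer vector of summed lengths.
#' @keywords internal
cigar_op_sum <- function(cigar, ops) {
  u <- unique(cigar)
  s <- vapply(u, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    if (!grepl(.CIGAR_RE, cg)) stop("malformed CIGAR string: ", cg)
    lens <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1L]])
    op <- regmatches(cg, gregexpr("[MIDNSHP=X]", cg))[[1L]]
    sum(lens[op %in% ops])
  }, integer(1L), USE.NAMES = FALSE)
  s[match(cigar, u)]
}

#' Number of query (read) bases consumed by a CIGAR string
#' @inheritParams cigar_op_sum
#' @return Integer vector; `NA` where `cigar == "*"`.
#' @export
cigar_query_len <- function(cigar) cigar_op_sum(cigar, c("M", "I", "S", "=", "X"))

#' Number of reference bases consumed by a CIGAR string
#' @inheritParams cigar_op_sum
#' @return Integer vector; `NA` where `cigar == "*"`.
#' @export
cigar_ref_len <- function(cigar) cigar_op_sum(cigar, c("M", "D", "N", "=", "X"))

# leading / trailing soft+hard clip lengths, vectorised
cigar_clip <- function(cigar, side = c("lead", "trail")) {
  side <- match.arg(side)
  u <- unique(cigar)
  s <- vapply(u, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    if (!grepl(.CIGAR_RE, cg)) stop("malformed CIGAR string: ", cg)
    lens <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1L]])
    op <- regmatches(cg, gregexpr("[MIDNSHP=X]", cg))[[1L]]
    if (side == "trail") { lens <- rev(lens); op <- rev(op) }
    tot <- 0L
    for (k in seq_along(op)) {
      if (op[k] %in% c("S", "H")) tot <- tot + lens[k] else break
    }
    tot
  }, integer(1L), USE.NAMES = FALSE)
  s[match(cigar, u)]
}

# ---- validation ------------------------------------------------------------

.violation <- function(row, column, rule) {
  data.frame(row = as.integer(row), column = column, rule = rule,
             stringsAsFactors = FALSE)
}

#' Validate a read batch against the columnar SAM invariants
#'
#' Checks, per row: non-negative `pos`/`pnext`, `mapq` in 0..255, `flag`
#' in 0..65535, CIGAR syntax, SEQ/QUAL length agreement, and agreement of
#' the CIGAR query-consumed length with the SEQ length.  Violations are
#' returned, not thrown, so callers can report all problems at once.
#'
#' @param batch a `read_batch`.
#' @return A data frame with columns `row` (0-based), `column`, `rule`;
#'   zero rows iff the batch satisfies every invariant.
#' @export
validate_batch <- function(batch) {
  stopifnot(is.data.frame(batch))
  out <- list()
  n <- nrow(batch)
  if (n == 0L) return(.violation(integer(), character(), character()))
  bad <- which(is.na(batch$pos) | batch$pos < 0L)
  if (length(bad)) out[[length(out) + 1L]] <-
    .violation(bad - 1L, "pos", "pos must be >= 0")
  bad <- which(is.na(batch$pnext) | batch$pnext < 0L)
  if (length(bad)) out[[length(out) + 1L]] <-
    .violation(bad - 1L, "pnext", "pnext must be >= 0")
  bad <- which(is.na(batch$mapq) | batch$mapq < 0L | batch$mapq > 255L)
  if (length(bad)) out[[length(out) + 1L]] <-
    .violation(bad - 1L, "mapq", "mapq must be in 0..255")
  bad <- which(is.na(batch$flag) | batch$flag < 0L | batch$flag > 65535L)
  if (length(bad)) out[[length(out) + 1L]] <-
    .violation(bad - 1L, "flag", "flag must be in 0..65535")
  cig_ok <- batch$cigar == "*" | grepl(.CIGAR_RE, batch$cigar)
  bad <- which(!cig_ok)
  if (length(bad)) out[[length(out) + 1L]] <-
    .violation(bad - 1L, "cigar", "cigar must be '*' or ([0-9]+[MIDNSHP=X])+")
  both <- which(batch$seq != "*" & batch$qual != "*")
  if (length(both)) {
    mism <- both[nchar(batch$seq[both]) != nchar(batch$qual[both])]
    if (length(mism)) out[[length(out) + 1L]] <-
      .violation(mism - 1L, "qual", "seq/qual length mismatch")
  }
  chk <- which(cig_ok & batch$cigar != "*" & batch$seq != "*")
  if (length(chk)) {
    ql <- cigar_query_len(batch$cigar[chk])
    mism <- chk[ql != nchar(batch$seq[chk])]
    if (length(mism)) out[[length(out) + 1L]] <-
      .violation(mism - 1L, "cigar",
                 "CIGAR query-consumed length differs from seq length")
  }
  if (!length(out)) return(.violation(integer(), character(), character()))
  out <- do.call(rbind, out)
  out[order(out$row, out$column), , drop = FALSE]
}

# ---- structural operations -------------------------------------------------

#' Concatenate read batches
#'
#' @param batches a list of `read_batch` objects sharing the standard
#'   twelve-column schema.
#' @return A single `read_batch`; rows appear in input order and column
#'   values are carried over unchanged.
#' @export
concat_batches <- function(batches) {
  if (!length(batches)) return(empty_read_batch())
  for (b in batches) {
    if (!identical(names(b), SAM_COLUMNS)) {
      off <- c(setdiff(SAM_COLUMNS, names(b)), setdiff(names(b), SAM_COLUMNS))
      stop("schema mismatch in concat_batches; offending column(s): ",
           paste(off, collapse = ", "))
    }
  }
  out <- do.call(rbind, lapply(batches, function(b) {
    class(b) <- "data.frame"
    b
  }))
  rownames(out) <- NULL
  class(out) <- c("read_batch", "data.frame")
  out
}

#' Gather rows of a batch by zero-based indices
#'
#' The gather primitive consumed by the INDEX delta column: output row
#' `k` equals input row `row_indices[k]` for every column.  Indices are
#' zero-based to match the on-disk INDEX contract.
#'
#' @param batch a `read_batch`.
#' @param row_indices integer vector of 0-based row indices, any order,
#'   repeats allowed.
#' @return A `read_batch` with `length(row_indices)` rows.
#' @export
slice_rows <- function(batch, row_indices) {
  n <- nrow(batch)
  row_indices <- as.integer(row_indices)
  bad <- row_indices < 0L | row_indices >= n | is.na(row_indices)
  if (any(bad))
    stop("slice_rows index out of range [0, ", n, "): ",
         row_indices[which(bad)[1L]])
  out <- batch[row_indices + 1L, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("read_batch", "data.frame")
  out
}

#' Deterministic in-memory size estimate of a batch
#'
#' Computed, not measured: character columns count value bytes plus
#' 4-byte offsets (n + 1 of them, as in a columnar string array); integer
#' columns count 4 bytes per value.  Platform-independent, so chunking
#' decisions are reproducible everywhere.
#'
#' @param batch a `read_batch`.
#' @return Estimated size in bytes (double, may exceed 2^31).
#' @export
approx_bytes <- function(batch) {
  n <- nrow(batch)
  sz <- 0
  for (col in .CHR_COLUMNS)
    sz <- sz + sum(nchar(batch[[col]], type = "bytes")) + 4 * (n + 1)
  for (col in .INT_COLUMNS)
    sz <- sz + 4 * n
  sz
}
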
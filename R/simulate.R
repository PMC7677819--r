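#' Synthetic aligned-read simulator with planted duplicate truth
#'
#' Generates SAM inputs with known structure so every pipeline stage is
#' testable without external datasets: background single-end and paired
#' reads at unique unclipped 5' ends, planted duplicate groups whose
#' members share unclipped end(s) and strand(s) by construction (members
#' may differ in soft-clip length, which is exactly the case unclipped
#' 5'-end grouping must handle), occasional cross-chromosome mates,
#' unmapped reads, and a uniformly shuffled record order.  One member of
#' every duplicate group is given maximal base qualities and the others
#' strictly lower ones, so the expected survivor is unambiguous and the
#' truth table does not depend on tie-breaking.
#'
#' @param references named integer vector of reference lengths; default
#'   a 25-reference human-style dictionary (chr1..chr22, chrX, chrY,
#'   chrM) at desk scale.
#' @param n_fragments number of background (non-duplicate) templates.
#' @param read_length read length in bases.
#' @param paired_fraction fraction of templates sequenced as pairs.
#' @param dup_groups number of planted duplicate groups.
#' @param dup_group_sizes integer vector of group sizes to sample from.
#' @param clip_prob per-read probability of a soft clip at the 5' end.
#' @param max_clip maximal soft-clip length.
#' @param cross_chrom_prob probability a background pair's mate maps to
#'   a different chromosome.
#' @param unmapped_fraction fraction of background templates emitted as
#'   unmapped reads.
#' @param qual_range Phred range (inclusive) for per-base background
#'   qualities; duplicate-group survivors are boosted to Phred 40, so
#'   the upper bound must stay below 40.
#' @param seed integer seed; the simulator restores the caller's RNG
#'   state on exit and identical specs yield byte-identical SAM.
#' @return A list with `header` ([sam_header]), `batch` ([read_batch],
#'   shuffled order), and `truth` (data frame: `qname`, `group_id`,
#'   `is_duplicate_expected`, one row per template).
#' @export
simulate_reads <- function(references = default_references(),
                           n_fragments = 1000L,
                           read_length = 100L,
                           paired_fraction = 0.6,
                           dup_groups = 50L,
                           dup_group_sizes = 2:5,
                           clip_prob = 0.3,
                           max_clip = 10L,
                           cross_chrom_prob = 0.01,
                           unmapped_fraction = 0.02,
                           qual_range = c(20L, 39L),
                           seed = 1L) {
  if (read_length > min(references))
    stop("read_length exceeds the shortest reference length")
  if (qual_range[2L] >= 40L || qual_range[1L] < 0L)
    stop("qual_range must lie in [0, 39] so group survivors are strict")
  insert_range <- c(250L, 350L)
  usable <- references[references >= 2L * read_length + 2L * max_clip +
                         insert_range[2L] + 20L]
  if (!length(usable))
    stop("no reference is long enough for the requested read geometry")

  if (exists(".Random.seed", envir = globalenv()))
    old_seed <- get(".Random.seed", envir = globalenv()) else old_seed <- NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  used <- new.env(parent = emptyenv())   # registry of reserved 5' ends
  lo <- read_length + max_clip + 2L
  reserve_end <- function(chrom, strand) {
    hi <- usable[[chrom]] - read_length - insert_range[2L] - max_clip - 2L
    repeat {
      u <- sample.int(hi - lo + 1L, 1L) + lo - 1L
      k <- paste0(chrom, ":", u, ":", strand)
      if (!exists(k, envir = used)) {
        assign(k, TRUE, envir = used)
        return(u)
      }
    }
  }
  rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
  rand_qual <- function(n)
    intToUtf8(sample.int(qual_range[2L] - qual_range[1L] + 1L, n,
                         replace = TRUE) + qual_range[1L] - 1L + 33L)
  best_qual <- function(n) strrep(intToUtf8(40L + 33L), n)
  clip_len <- function()
    if (stats::runif(1L) < clip_prob) sample.int(max_clip, 1L) else 0L

  cap <- 2L * (dup_groups * max(dup_group_sizes) + n_fragments)
  rows <- vector("list", cap)
  truth <- vector("list", cap)
  n_rows <- 0L
  n_truth <- 0L
  emit <- function(qname, flag, rname, pos, mapq, cigar, rnext, pnext,
                   tlen, sq, ql, tags) {
    n_rows <<- n_rows + 1L
    rows[[n_rows]] <<- list(qname = qname, flag = flag,
                            rname = rname, pos = pos,
                            mapq = mapq, cigar = cigar,
                            rnext = rnext, pnext = pnext,
                            tlen = tlen, seq = sq, qual = ql,
                            tags = tags)
  }
  note <- function(qname, group_id, dup) {
    n_truth <<- n_truth + 1L
    truth[[n_truth]] <<- list(qname = qname,
                              group_id = group_id,
                              is_duplicate_expected = dup)
  }
  L <- read_length
  chrom_names <- names(usable)
  chrom_w <- as.numeric(usable) / sum(as.numeric(usable))

  # forward read anchored at unclipped end u: POS = u + clip
  fwd_read <- function(u, c) list(pos = u + c,
                                  cigar = if (c > 0L)
                                    paste0(c, "S", L - c, "M")
                                  else paste0(L, "M"))
  # reverse read anchored at unclipped end u: POS = u - L + 1 regardless
  # of the trailing clip (clipping shortens the aligned block, not POS)
  rev_read <- function(u, c) list(pos = u - L + 1L,
                                  cigar = if (c > 0L)
                                    paste0(L - c, "M", c, "S")
                                  else paste0(L, "M"))

  emit_pair <- function(qname, chrom1, u1, chrom2, u2, q1, q2) {
    c1 <- clip_len(); c2 <- clip_len()
    r1 <- fwd_read(u1, c1)           # first mate forward at u1
    r2 <- rev_read(u2, c2)           # second mate reverse at u2
    same <- chrom1 == chrom2
    tl <- if (same) u2 - u1 + 1L else 0L
    proper <- if (same) 0x2L else 0L
    emit(qname, bitwOr(0x1L + 0x20L + 0x40L, proper), chrom1, r1$pos, 60L,
         r1$cigar, if (same) "=" else chrom2, r2$pos, tl,
         rand_seq(L), q1, paste0("MC:Z:", r2$cigar))
    emit(qname, bitwOr(0x1L + 0x10L + 0x80L, proper), chrom2, r2$pos, 60L,
         r2$cigar, if (same) "=" else chrom1, r1$pos, if (same) -tl else 0L,
         rand_seq(L), q2, paste0("MC:Z:", r1$cigar))
  }
  emit_single <- function(qname, chrom, u, strand, q) {
    c <- clip_len()
    r <- if (strand == "F") fwd_read(u, c) else rev_read(u, c)
    emit(qname, if (strand == "R") 0x10L else 0L, chrom, r$pos, 60L,
         r$cigar, "*", 0L, 0L, rand_seq(L), q, "")
  }

  # ---- planted duplicate groups ----
  for (g in seq_len(dup_groups)) {
    gid <- sprintf("g%04d", g)
    chrom <- sample(chrom_names, 1L, prob = chrom_w)
    size <- if (length(dup_group_sizes) == 1L) dup_group_sizes
            else sample(dup_group_sizes, 1L)
    paired <- stats::runif(1L) < paired_fraction
    if (paired) {
      u1 <- reserve_end(chrom, "F")
      u2 <- u1 + sample.int(insert_range[2L] - insert_range[1L] + 1L, 1L) +
        insert_range[1L] - 1L
      k2 <- paste0(chrom, ":", u2, ":R")
      while (exists(k2, envir = used)) {
        u2 <- u2 + 1L
        k2 <- paste0(chrom, ":", u2, ":R")
      }
      assign(k2, TRUE, envir = used)
      for (j in seq_len(size)) {
        qn <- sprintf("dup%04d_%02d", g, j)
        ql <- if (j == 1L) best_qual(L) else rand_qual(L)
        qr <- if (j == 1L) best_qual(L) else rand_qual(L)
        emit_pair(qn, chrom, u1, chrom, u2, ql, qr)
        note(qn, gid, j != 1L)
      }
    } else {
      strand <- sample(c("F", "R"), 1L)
      u <- reserve_end(chrom, strand)
      for (j in seq_len(size)) {
        qn <- sprintf("dup%04d_%02d", g, j)
        ql <- if (j == 1L) best_qual(L) else rand_qual(L)
        emit_single(qn, chrom, u, strand, ql)
        note(qn, gid, j != 1L)
      }
    }
  }

  # ---- background templates ----
  for (i in seq_len(n_fragments)) {
    qn <- sprintf("sim%06d", i)
    if (stats::runif(1L) < unmapped_fraction) {
      emit(qn, 0x4L, "*", 0L, 0L, "*", "*", 0L, 0L, rand_seq(L),
           rand_qual(L), "")
      note(qn, NA_character_, FALSE)
      next
    }
    chrom <- sample(chrom_names, 1L, prob = chrom_w)
    if (stats::runif(1L) < paired_fraction) {
      if (stats::runif(1L) < cross_chrom_prob && length(chrom_names) > 1L) {
        chrom2 <- sample(setdiff(chrom_names, chrom), 1L)
        u1 <- reserve_end(chrom, "F")
        u2 <- reserve_end(chrom2, "R")
        emit_pair(qn, chrom, u1, chrom2, u2, rand_qual(L), rand_qual(L))
      } else {
        u1 <- reserve_end(chrom, "F")
        u2 <- u1 + sample.int(insert_range[2L] - insert_range[1L] + 1L,
                              1L) + insert_range[1L] - 1L
        k2 <- paste0(chrom, ":", u2, ":R")
        while (exists(k2, envir = used)) {
          u2 <- u2 + 1L
          k2 <- paste0(chrom, ":", u2, ":R")
        }
        assign(k2, TRUE, envir = used)
        emit_pair(qn, chrom, u1, chrom, u2, rand_qual(L), rand_qual(L))
      }
    } else {
      strand <- sample(c("F", "R"), 1L)
      u <- reserve_end(chrom, strand)
      emit_single(qn, chrom, u, strand, rand_qual(L))
    }
    note(qn, NA_character_, FALSE)
  }

  # ---- assemble, shuffle, package ----
  rows <- rows[seq_len(n_rows)]
  truth <- truth[seq_len(n_truth)]
  get_col <- function(nm, mode) {
    v <- vapply(rows, `[[`, vector(mode, 1L), nm)
    v
  }
  batch <- read_batch(qname = get_col("qname", "character"),
                      flag = get_col("flag", "integer"),
                      rname = get_col("rname", "character"),
                      pos = get_col("pos", "integer"),
                      mapq = get_col("mapq", "integer"),
                      cigar = get_col("cigar", "character"),
                      rnext = get_col("rnext", "character"),
                      pnext = get_col("pnext", "integer"),
                      tlen = get_col("tlen", "integer"),
                      seq = get_col("seq", "character"),
                      qual = get_col("qual", "character"),
                      tags = get_col("tags", "character"))
  batch <- slice_df(batch, sample.int(nrow(batch)))
  truth_df <- data.frame(
    qname = vapply(truth, `[[`, character(1L), "qname"),
    group_id = vapply(truth, `[[`, character(1L), "group_id"),
    is_duplicate_expected = vapply(truth, `[[`, logical(1L),
                                   "is_duplicate_expected"),
    stringsAsFactors = FALSE)
  list(header = make_header(references, sort_order = "unknown"),
       batch = batch, truth = truth_df)
}

#' Desk-scale human-style reference dictionary
#'
#' 25 references named as the human assembly (chr1..chr22, chrX, chrY,
#' chrM) with lengths scaled down to desk size but keeping the familiar
#' ordering and rough relative proportions (chrM tiny, autosomes
#' decreasing).
#'
#' @return Named integer vector of reference lengths.
#' @export
default_references <- function() {
  auto <- round(seq(1500000L, 400000L, length.out = 22L))
  stats::setNames(as.integer(c(auto, 1000000L, 300000L, 16571L)),
                  c(paste0("chr", 1:22), "chrX", "chrY", "chrM"))
}

#' Write a simulation to disk
#'
#' @param sim result of [simulate_reads].
#' @param sam_path output SAM path.
#' @param truth_path optional TSV path for the truth table.
#' @return Invisibly, `sam_path`.
#' @export
write_simulation <- function(sim, sam_path, truth_path = NULL) {
  write_sam(sim$header, sim$batch, sam_path)
  if (!is.null(truth_path))
    utils::write.table(sim$truth, truth_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(sam_path)
}
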
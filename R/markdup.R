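#' Duplicate marking on the columnar representation
#'
#' Reads that share unclipped 5' end(s) and strand(s) are duplicate
#' candidates of each other; in every such group the highest-scoring
#' member survives and all others get FLAG bit 0x400 set.  Marking is
#' emitted as a *FLAG delta* -- a replacement FLAG column per chunk --
#' rather than rewriting the batch, so downstream stages merge the
#' updated flags with the untouched source columns.
#'
#' @name markdup
NULL

#' FLAG delta column
#' @param flags integer vector of replacement FLAG values, one per owned
#'   row of the chunk it belongs to; may differ from the source flags
#'   only in bit 0x400.
#' @return A `flag_delta`.
#' @export
flag_delta <- function(flags) {
  structure(list(flags = as.integer(flags)), class = "flag_delta")
}

#' Unclipped 5' end of an alignment
#'
#' The grouping coordinate for duplicate detection: the position the
#' first sequenced base would map to had it not been soft/hard-clipped.
#' Forward strand: `pos` minus leading S/H lengths.  Reverse strand: the
#' rightmost reference position (`pos` + reference-consumed length - 1)
#' plus trailing S/H lengths.
#'
#' @param pos 1-based leftmost mapping position(s), >= 1.
#' @param cigar CIGAR string(s), not `"*"`.
#' @param strand `"F"` or `"R"`, recycled.
#' @return Integer vector of unclipped 5' end positions.
#' @export
unclipped_5p <- function(pos, cigar, strand) {
  if (any(pos < 1L)) stop("unclipped_5p requires pos >= 1")
  if (any(cigar == "*")) stop("unclipped_5p requires cigar != '*'")
  n <- max(length(pos), length(cigar), length(strand))
  pos <- rep_len(as.integer(pos), n)
  cigar <- rep_len(cigar, n)
  strand <- rep_len(strand, n)
  out <- integer(n)
  fwd <- strand == "F"
  if (any(fwd))
    out[fwd] <- pos[fwd] - cigar_clip(cigar[fwd], "lead")
  if (any(!fwd))
    out[!fwd] <- pos[!fwd] + cigar_ref_len(cigar[!fwd]) - 1L +
      cigar_clip(cigar[!fwd], "trail")
  out
}

#' Duplicate-survivor score of a read
#'
#' Strategy `"sum_of_base_qualities"` (the Picard-style default): the
#' sum of Phred base qualities over bases with Phred >= 15.  Strategy
#' `"total_mapped_length"`: the number of query bases consumed by
#' M/=/X operations.
#'
#' @param qual Phred+33 quality string(s); required for the base-quality
#'   strategy (`"*"` scores 0).
#' @param cigar CIGAR string(s); required for the mapped-length
#'   strategy.
#' @param strategy one of `"sum_of_base_qualities"`,
#'   `"total_mapped_length"`.
#' @return Integer vector of scores.
#' @export
duplicate_score <- function(qual = NULL, cigar = NULL,
                            strategy = c("sum_of_base_qualities",
                                         "total_mapped_length")) {
  strategy <- match.arg(strategy)
  if (strategy == "sum_of_base_qualities") {
    if (is.null(qual)) stop("base-quality scoring requires qual")
    vapply(qual, function(q) {
      if (is.na(q) || q == "*") return(0L)
      ph <- utf8ToInt(q) - 33L
      sum(ph[ph >= 15L])
    }, integer(1L), USE.NAMES = FALSE)
  } else {
    if (is.null(cigar)) stop("mapped-length scoring requires cigar")
    out <- cigar_op_sum(cigar, c("M", "=", "X"))
    out[is.na(out)] <- 0L
    out
  }
}

# extract MC:Z: (mate CIGAR) tag values from the tags column; NA if absent
.mc_tag <- function(tags) {
  out <- rep(NA_character_, length(tags))
  hit <- lengths(regmatches(tags, gregexpr("MC:Z:", tags))) > 0L
  out[hit] <- sub(".*MC:Z:([0-9MIDNSHP=X]+).*", "\\1", tags[hit])
  out
}

# per-row duplicate-candidate geometry for all rows of a batch
.dup_geometry <- function(batch, scoring) {
  flag <- batch$flag
  cand <- bitwAnd(flag, 0x4L) == 0L & bitwAnd(flag, 0x100L) == 0L &
    bitwAnd(flag, 0x800L) == 0L & batch$cigar != "*" & batch$pos >= 1L
  n <- nrow(batch)
  strand <- ifelse(bitwAnd(flag, 0x10L) > 0L, "R", "F")
  self5 <- rep(NA_integer_, n)
  if (any(cand))
    self5[cand] <- unclipped_5p(batch$pos[cand], batch$cigar[cand],
                                strand[cand])
  paired <- cand & bitwAnd(flag, 0x1L) > 0L & bitwAnd(flag, 0x8L) == 0L &
    batch$rnext != "*"
  mate_chrom <- ifelse(batch$rnext == "=", batch$rname, batch$rnext)
  mate_strand <- ifelse(bitwAnd(flag, 0x20L) > 0L, "R", "F")
  mc <- .mc_tag(batch$tags)
  mate5 <- rep(NA_integer_, n)
  mc_missing <- 0L
  pp <- which(paired)
  if (length(pp)) {
    has_mc <- !is.na(mc[pp])
    if (any(has_mc))
      mate5[pp[has_mc]] <- unclipped_5p(batch$pnext[pp[has_mc]],
                                        mc[pp[has_mc]],
                                        mate_strand[pp[has_mc]])
    # without the mate CIGAR the mate's clipping cannot be corrected for;
    # fall back to PNEXT and count the fallback
    mate5[pp[!has_mc]] <- batch$pnext[pp[!has_mc]]
    mc_missing <- sum(!has_mc)
  }
  score <- integer(n)
  ci <- which(cand)
  if (length(ci))
    score[ci] <- duplicate_score(qual = batch$qual[ci],
                                 cigar = batch$cigar[ci],
                                 strategy = scoring)
  # canonical pair key: lexicographically smaller (chrom, u5, strand)
  # end first, so both mates of a pair compute the same key independently
  e1 <- sprintf("%s:%d:%s", batch$rname, self5, strand)
  e2 <- sprintf("%s:%d:%s", mate_chrom, mate5, mate_strand)
  lo <- ifelse(e1 <= e2, e1, e2)
  hi <- ifelse(e1 <= e2, e2, e1)
  pair_key <- ifelse(paired, paste(lo, hi, "P", sep = "|"), NA_character_)
  frag_key <- ifelse(cand & !paired, paste(e1, "F", sep = "|"),
                     NA_character_)
  list(cand = cand, paired = paired, strand = strand, self5 = self5,
       score = score, pair_key = pair_key, frag_key = frag_key,
       self_end = ifelse(cand, e1, NA_character_),
       mc_missing = mc_missing)
}

# pair score per qname: sum of both primary mates' scores where present
.pair_scores <- function(batch, scoring) {
  g <- .dup_geometry(batch, scoring)
  pp <- which(g$paired)
  if (!length(pp)) return(numeric())
  tapply(g$score[pp], batch$qname[pp], sum)
}

#' Mark duplicates within one chunk
#'
#' Candidate rows (primary, mapped, not secondary/supplementary) are
#' grouped by their duplicate key: paired reads by the canonical pair of
#' (chromosome, unclipped 5' end, strand) ends, unpaired reads by their
#' single end.  In every group with two or more members the
#' highest-scoring member is left unmarked and all others get bit 0x400
#' set; ties break deterministically by (score desc, qname asc).  An
#' unpaired read whose end coincides with any paired read's end is
#' always marked (a fragment duplicates a pair).  Padding rows take part
#' in grouping and scoring but receive no output flags -- their owning
#' chunk decides them.
#'
#' @param chunk a sorted [sam_chunk], padding included.
#' @param config list: `scoring` (see [duplicate_score]); optionally
#'   `pair_scores`, a named vector of per-qname pair scores computed
#'   over the whole partition (used so chunking cannot change pair
#'   scores when mates land in different chunks).
#' @return A [flag_delta] over the chunk's owned rows, with attributes
#'   `n_marked` (0x400 transitions 0 -> 1) and `mc_missing` (paired
#'   candidates lacking an MC tag, whose mate clipping could not be
#'   corrected for).
#' @export
mark_duplicates_chunk <- function(chunk,
                                  config = list(scoring =
                                                  "sum_of_base_qualities")) {
  stopifnot(inherits(chunk, "sam_chunk"))
  if (!chunk$sorted) stop("mark_duplicates_chunk requires a sorted chunk")
  scoring <- config$scoring %||% "sum_of_base_qualities"
  batch <- chunk$batch
  n <- nrow(batch)
  g <- .dup_geometry(batch, scoring)
  # entity score: pairs score as the mate sum, fragments as their own score
  pair_sc <- config$pair_scores
  ent_score <- g$score
  pp <- which(g$paired)
  if (length(pp)) {
    if (is.null(pair_sc))
      pair_sc <- tapply(g$score[pp], batch$qname[pp], sum)
    ent_score[pp] <- as.numeric(pair_sc[batch$qname[pp]])
  }
  marked <- rep(FALSE, n)
  # paired groups: entities are qnames sharing a canonical pair key
  if (length(pp)) {
    ent <- data.frame(key = g$pair_key[pp], qname = batch$qname[pp],
                      score = ent_score[pp], stringsAsFactors = FALSE)
    ent <- unique(ent)
    winners <- vapply(split(ent, ent$key), function(d) {
      d <- d[order(-d$score, d$qname), , drop = FALSE]
      d$qname[1L]
    }, character(1L))
    gsz <- table(ent$key)
    multi <- names(gsz)[gsz >= 2L]
    loser <- g$pair_key[pp] %in% multi &
      batch$qname[pp] != winners[g$pair_key[pp]]
    marked[pp[loser]] <- TRUE
  }
  # fragment rule: a fragment at any paired read's end is always marked;
  # otherwise fragments compete among themselves
  fi <- which(g$cand & !g$paired)
  if (length(fi)) {
    paired_ends <- unique(g$self_end[pp])
    at_pair <- g$self_end[fi] %in% paired_ends
    marked[fi[at_pair]] <- TRUE
    rest <- fi[!at_pair]
    if (length(rest)) {
      ent <- data.frame(key = g$frag_key[rest], qname = batch$qname[rest],
                        score = ent_score[rest],
                        row = rest, stringsAsFactors = FALSE)
      for (d in split(ent, ent$key)) {
        if (nrow(d) < 2L) next
        d <- d[order(-d$score, d$qname), , drop = FALSE]
        marked[d$row[-1L]] <- TRUE
      }
    }
  }
  own <- seq.int(chunk$n_pad_head + 1L,
                 length.out = n - chunk$n_pad_head - chunk$n_pad_tail)
  flags_out <- batch$flag[own]
  flags_out[marked[own]] <- bitwOr(flags_out[marked[own]], 0x400L)
  delta <- flag_delta(flags_out)
  attr(delta, "n_marked") <- sum(bitwAnd(batch$flag[own], 0x400L) == 0L &
                                   bitwAnd(flags_out, 0x400L) > 0L)
  attr(delta, "mc_missing") <- g$mc_missing
  delta
}

#' Mark duplicates across the whole store, chromosome-parallel
#'
#' For every chromosome in the `"sorted"` namespace, pair scores are
#' first computed over the whole partition (so results do not depend on
#' chunk boundaries), then each chunk is marked independently and its
#' FLAG delta sealed under `"flagdelta"`.  The unmapped `"*"` partition
#' is never marked.  Outputs are independent of the worker count.
#'
#' @param store an `object_store`.
#' @param header a [sam_header].
#' @param workers number of parallel workers.
#' @param config see [mark_duplicates_chunk].
#' @param in_namespace,out_namespace store namespaces.
#' @return Named integer vector: duplicates newly marked per chromosome.
#' @export
mark_duplicates_all <- function(store, header, workers = 1L,
                                config = list(scoring =
                                                "sum_of_base_qualities"),
                                in_namespace = "sorted",
                                out_namespace = "flagdelta") {
  keys <- store_keys(store, in_namespace, header = header)
  if (!length(keys)) stop("no objects in namespace '", in_namespace, "'")
  chroms <- unique(vapply(keys, `[[`, character(1L), "chrom"))
  chroms <- chroms[order(match(chroms, chrom_order(header)))]
  res <- .chrom_lapply(chroms, workers, function(chrom) {
    if (chrom == "*") return(0L)
    ck <- Filter(function(k) k$chrom == chrom, keys)
    ck <- ck[order(vapply(ck, `[[`, integer(1L), "ordinal"))]
    chunks <- lapply(ck, function(k) store_get(store, k))
    whole <- concat_batches(lapply(chunks, owned_rows))
    cfg <- config
    cfg$pair_scores <- .pair_scores(whole, config$scoring %||%
                                      "sum_of_base_qualities")
    marked <- 0L
    for (ch in chunks) {
      delta <- mark_duplicates_chunk(ch, cfg)
      store_put(store, object_key(out_namespace, chrom, ch$ordinal), delta)
      marked <- marked + attr(delta, "n_marked")
    }
    marked
  })
  stats::setNames(as.integer(unlist(res)),
                  chroms)[chroms != "*"]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
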
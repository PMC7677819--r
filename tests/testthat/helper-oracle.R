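# Independent brute-force duplicate-marking oracle.
#
# Deliberately naive and written from the definitions alone: character-by-
# character CIGAR walking, all-pairs entity clustering, no shared code with
# the package implementation.  O(n^2); only for small inputs.

oracle_cigar_walk <- function(cigar) {
  nums <- integer(); ops <- character(); cur <- ""
  for (ch in strsplit(cigar, "")[[1L]]) {
    if (ch >= "0" && ch <= "9") cur <- paste0(cur, ch)
    else { nums <- c(nums, as.integer(cur)); ops <- c(ops, ch); cur <- "" }
  }
  list(nums = nums, ops = ops)
}

oracle_unclipped <- function(pos, cigar, reverse) {
  w <- oracle_cigar_walk(cigar)
  if (!reverse) {
    clip <- 0L
    for (k in seq_along(w$ops)) {
      if (w$ops[k] == "S" || w$ops[k] == "H") clip <- clip + w$nums[k]
      else break
    }
    pos - clip
  } else {
    ref <- sum(w$nums[w$ops %in% c("M", "D", "N", "=", "X")])
    clip <- 0L
    for (k in rev(seq_along(w$ops))) {
      if (w$ops[k] == "S" || w$ops[k] == "H") clip <- clip + w$nums[k]
      else break
    }
    pos + ref - 1L + clip
  }
}

oracle_score <- function(qual) {
  if (qual == "*") return(0L)
  v <- utf8ToInt(qual) - 33L
  s <- 0L
  for (x in v) if (x >= 15L) s <- s + x
  s
}

oracle_mc <- function(tags) {
  for (t in strsplit(tags, "\t")[[1L]])
    if (substr(t, 1L, 5L) == "MC:Z:") return(substring(t, 6L))
  NA_character_
}

# marked-row logical vector for one whole dataset (all chromosomes)
oracle_mark_duplicates <- function(batch) {
  n <- nrow(batch)
  marked <- rep(FALSE, n)
  ends <- vector("list", n)       # self end: list(chrom, u5, rev)
  mates <- vector("list", n)      # mate end, or NULL
  cand <- rep(FALSE, n)
  paired <- rep(FALSE, n)
  score <- integer(n)
  for (i in seq_len(n)) {
    f <- batch$flag[i]
    if (f %/% 4 %% 2 == 1 || f %/% 256 %% 2 == 1 ||
        f %/% 2048 %% 2 == 1) next
    if (batch$cigar[i] == "*" || batch$pos[i] < 1L) next
    cand[i] <- TRUE
    rev <- f %/% 16 %% 2 == 1
    ends[[i]] <- list(chrom = batch$rname[i],
                      u5 = oracle_unclipped(batch$pos[i], batch$cigar[i],
                                            rev),
                      rev = rev)
    score[i] <- oracle_score(batch$qual[i])
    if (f %/% 1 %% 2 == 1 && f %/% 8 %% 2 == 0 && batch$rnext[i] != "*") {
      paired[i] <- TRUE
      mrev <- f %/% 32 %% 2 == 1
      mchrom <- if (batch$rnext[i] == "=") batch$rname[i] else batch$rnext[i]
      mc <- oracle_mc(batch$tags[i])
      mu5 <- if (!is.na(mc)) oracle_unclipped(batch$pnext[i], mc, mrev)
             else batch$pnext[i]
      mates[[i]] <- list(chrom = mchrom, u5 = mu5, rev = mrev)
    }
  }
  same_end <- function(a, b)
    a$chrom == b$chrom && a$u5 == b$u5 && a$rev == b$rev
  # pair score per qname: sum of candidate paired rows within a chromosome
  pair_score <- function(qn, chrom) {
    s <- 0L
    for (i in seq_len(n))
      if (paired[i] && batch$qname[i] == qn && batch$rname[i] == chrom)
        s <- s + score[i]
    s
  }
  # ---- paired entities, per chromosome ----
  for (chrom in unique(batch$rname[paired])) {
    idx <- which(paired & batch$rname == chrom)
    qns <- unique(batch$qname[idx])
    rep_row <- vapply(qns, function(q) idx[batch$qname[idx] == q][1L],
                      integer(1L))
    g <- length(qns)
    cluster <- seq_len(g)
    for (a in seq_len(g)) for (b in seq_len(g)) {
      if (a >= b) next
      ia <- rep_row[a]; ib <- rep_row[b]
      # unordered comparison of the two end sets
      ea <- list(ends[[ia]], mates[[ia]])
      eb <- list(ends[[ib]], mates[[ib]])
      eq <- (same_end(ea[[1L]], eb[[1L]]) && same_end(ea[[2L]], eb[[2L]])) ||
        (same_end(ea[[1L]], eb[[2L]]) && same_end(ea[[2L]], eb[[1L]]))
      if (eq) cluster[cluster == cluster[b]] <- cluster[a]
    }
    for (cl in unique(cluster)) {
      members <- qns[cluster == cl]
      if (length(members) < 2L) next
      sc <- vapply(members, pair_score, integer(1L), chrom = chrom)
      best <- members[order(-sc, members)][1L]
      for (q in setdiff(members, best))
        marked[paired & batch$qname == q & batch$rname == chrom] <- TRUE
    }
  }
  # ---- fragments ----
  frag <- which(cand & !paired)
  for (i in frag) {
    hit_pair <- FALSE
    for (j in which(paired))
      if (batch$rname[j] == batch$rname[i] &&
          same_end(ends[[j]], ends[[i]])) { hit_pair <- TRUE; break }
    if (hit_pair) { marked[i] <- TRUE; next }
  }
  frag <- frag[!marked[frag]]
  done <- rep(FALSE, length(frag))
  for (a in seq_along(frag)) {
    if (done[a]) next
    grp <- frag[a]
    for (b in seq_along(frag)) {
      if (b == a || done[b]) next
      if (batch$rname[frag[b]] == batch$rname[frag[a]] &&
          same_end(ends[[frag[b]]], ends[[frag[a]]])) {
        grp <- c(grp, frag[b]); done[b] <- TRUE
      }
    }
    done[a] <- TRUE
    if (length(grp) < 2L) next
    best <- grp[order(-score[grp], batch$qname[grp])][1L]
    marked[setdiff(grp, best)] <- TRUE
  }
  marked
}

# independent stable coordinate-sort oracle: sort (pos, original rank)
oracle_sort <- function(batch) {
  key <- batch$pos * (nrow(batch) + 1) + (seq_len(nrow(batch)) - 1L)
  batch[order(key), , drop = FALSE]
}
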
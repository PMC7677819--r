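iv_chunk <- function(pos, cigar, chrom = "chr1") {
  n <- length(pos)
  L <- cigar_query_len(cigar)
  L[is.na(L)] <- 10L
  b <- read_batch(qname = sprintf("r%02d", seq_len(n)),
                  flag = integer(n), rname = rep(chrom, n),
                  pos = as.integer(pos), mapq = rep(60L, n),
                  cigar = cigar, rnext = rep("*", n),
                  pnext = integer(n), tlen = integer(n),
                  seq = strrep("A", L), qual = strrep("I", L),
                  tags = character(n))
  o <- order(b$pos)
  sam_chunk(slice_rows(b, o - 1L), chrom, sorted = TRUE)
}

test_that("stage views expose exactly the stage's column sets", {
  ch <- iv_chunk(c(100L, 200L), c("10M", "10M"))
  fd <- flag_delta(c(0L, 1024L))
  qd <- qual_index_delta("IIIIIIIIII", 1L)
  expect_equal(names(stage_view(ch, "markdup")$columns),
               c("QNAME", "FLAG", "RNAME", "POS", "CIGAR", "RNEXT"))
  v_bqsr <- stage_view(ch, "bqsr", flagdelta = fd)
  expect_equal(names(v_bqsr$columns),
               c("RNAME", "POS", "MAPQ", "CIGAR", "SEQ", "QUAL", "FLAG"))
  expect_length(v_bqsr$columns, 7L)
  expect_equal(v_bqsr$columns$FLAG, c(0L, 1024L))  # merged, not source
  v_hc <- stage_view(ch, "haplotypecaller", flagdelta = fd,
                     qualindex = qd)
  expect_equal(names(v_hc$columns),
               c("RNAME", "POS", "MAPQ", "CIGAR", "SEQ", "FLAG", "QUAL",
                 "INDEX"))
  expect_length(v_hc$columns, 8L)
  expect_equal(v_hc$columns$INDEX, 1L)
  expect_equal(v_hc$columns$QUAL, "IIIIIIIIII")
})

test_that("stage views refuse to build without their required deltas", {
  ch <- iv_chunk(100L, "10M")
  expect_error(stage_view(ch, "bqsr"), "flagdelta")
  expect_error(stage_view(ch, "haplotypecaller",
                          flagdelta = flag_delta(0L)), "qualindex")
})

test_that("interval overlap uses the reference span, 1-based inclusive", {
  iv <- interval_set(data.frame(chrom = "chr1", start = 100L, end = 200L))
  # span 150..249 overlaps 101..200
  expect_equal(filter_by_intervals(iv_chunk(150L, "100M"), iv), 0L)
  # span 300..349 does not
  expect_length(filter_by_intervals(iv_chunk(300L, "50M"), iv), 0L)
  # a read ending exactly on the first interval base (101) overlaps
  expect_equal(filter_by_intervals(iv_chunk(92L, "10M1S"), iv), 0L)
  # one base short of the interval does not
  expect_length(filter_by_intervals(iv_chunk(91L, "10M1S"), iv), 0L)
  # deletions extend the span: pos 95, 5M10D5M spans 95..114
  expect_equal(filter_by_intervals(iv_chunk(95L, "5M10D5M"), iv), 0L)
  # unmapped-style rows never survive
  expect_length(filter_by_intervals(iv_chunk(150L, "*"), iv), 0L)
  expect_length(filter_by_intervals(iv_chunk(150L, "100M"),
                                    interval_set()), 0L)
})

test_that("apply_qual_transform maps per-base Phred values", {
  ch <- iv_chunk(c(100L, 200L, 300L), c("4M", "4M", "4M"))
  # identity keeps the source strings
  d <- apply_qual_transform(ch, 0:2, identity)
  expect_equal(d$qual, owned_rows(ch)$qual)
  # constant Phred 30 is '?' (30 + 33 = 63)
  d30 <- apply_qual_transform(ch, c(0L, 2L),
                              function(p) rep(30L, length(p)))
  expect_equal(d30$qual, c("????", "????"))
  expect_equal(d30$index, c(0L, 2L))
  expect_equal(length(apply_qual_transform(ch, integer())$index), 0L)
  expect_error(apply_qual_transform(ch, 0L, function(p) p + 100L),
               "0\\.\\.93")
  expect_error(apply_qual_transform(ch, 5L, identity), "range")
})

test_that("qual_index_delta enforces its invariants", {
  expect_error(qual_index_delta("II", c(1L, 1L)), "length|increasing")
  expect_error(qual_index_delta(c("I", "I"), c(2L, 1L)), "increasing")
  expect_error(qual_index_delta("I", -1L), ">= 0")
})

test_that("resolve_reads equals slice_rows with flag/qual substituted", {
  sim <- sim_small(n_fragments = 400L, dup_groups = 10L, seed = 23L)
  parts <- partition_by_chrom(sim$header, sim$batch)
  chrom <- names(which.max(vapply(parts, nrow, integer(1L))))
  p <- sort_partition(sam_partition(chrom,
                                    list(sam_chunk(parts[[chrom]], chrom))))
  ch <- p$chunks[[1L]]
  src <- owned_rows(ch)
  iv <- interval_set(data.frame(chrom = chrom,
                                start = seq(0L, 900000L, by = 40000L),
                                end = seq(0L, 900000L, by = 40000L) +
                                  8000L))
  idx <- filter_by_intervals(ch, iv)
  expect_gt(length(idx), 0L)
  expect_true(all(diff(idx) > 0L))
  fd <- mark_duplicates_chunk(ch)
  cap35 <- function(p) pmin(p, 35L)
  qd <- apply_qual_transform(ch, idx, cap35)
  got <- resolve_reads(ch, fd, qd)
  # compositional oracle, column by column
  want <- slice_rows(src, idx)
  want$flag <- fd$flags[idx + 1L]
  want$qual <- vapply(want$qual, function(q)
    intToUtf8(pmin(utf8ToInt(q) - 33L, 35L) + 33L), character(1L))
  for (col in SAM_COLUMNS) expect_equal(got[[col]], want[[col]])
  # rows outside every interval never appear in the resolved batch
  outside <- src$qname[setdiff(seq_len(nrow(src)), idx + 1L)]
  kept_only_inside <- setdiff(outside, src$qname[idx + 1L])
  expect_false(any(got$qname %in% kept_only_inside))
  expect_equal(qd$index, idx)
  # order preserved: resolved batch is sorted whenever the source is
  expect_false(is.unsorted(got$pos))
})

test_that("identity deltas reproduce the source with updated flags", {
  ch <- iv_chunk(c(10L, 20L), c("4M", "4M"))
  src <- owned_rows(ch)
  fd <- flag_delta(c(1024L, 0L))
  out <- resolve_reads(ch, fd, NULL)
  expect_equal(out$flag, c(1024L, 0L))
  expect_equal(out$qname, src$qname)
  # empty index -> empty batch
  expect_equal(nrow(resolve_reads(ch, fd, qual_index_delta())), 0L)
  # a delta touching other flag bits is rejected
  expect_error(resolve_reads(ch, flag_delta(c(3L, 0L)), NULL), "0x400")
})

test_that("export_final writes per-chromosome files plus unmapped", {
  sim <- simulate_reads(references = c(chr1 = 200000L, chr2 = 200000L,
                                       chr3 = 200000L),
                        n_fragments = 120L, dup_groups = 5L,
                        unmapped_fraction = 0.1, seed = 29L)
  samf <- tempfile(fileext = ".sam")
  write_simulation(sim, samf)
  prefix <- tempfile("percontig_")
  rep <- run_pipeline(list(input = samf, out = prefix, per_chrom = TRUE))
  expect_length(rep$files, 4L)
  expect_true(any(grepl("unmapped", rep$files)))
  total <- sum(vapply(rep$files, function(f) length(aln_lines(f)),
                      integer(1L)))
  expect_equal(total, nrow(sim$batch))
})
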
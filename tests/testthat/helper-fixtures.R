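# small handcrafted fixtures used across test files

tiny_header <- function() make_header(c(chr1 = 100000L, chr2 = 80000L))

# a 3-row batch on chr1 with distinct positions
tiny_batch <- function() {
  read_batch(
    qname = c("a", "b", "c"), flag = c(0L, 16L, 0L),
    rname = rep("chr1", 3L), pos = c(100L, 300L, 200L),
    mapq = rep(60L, 3L), cigar = rep("4M", 3L),
    rnext = rep("*", 3L), pnext = rep(0L, 3L), tlen = rep(0L, 3L),
    seq = rep("ACGT", 3L), qual = rep("IIII", 3L),
    tags = c("NM:i:0", "", ""))
}

# simulator call small enough for fast unit tests
sim_small <- function(n_fragments = 200L, dup_groups = 15L, seed = 42L,
                      ...) {
  simulate_reads(n_fragments = n_fragments, dup_groups = dup_groups,
                 seed = seed, ...)
}

# run the standard pipeline on a simulation, returning report + output
run_sim_pipeline <- function(sim, ..., bed = NULL) {
  samf <- tempfile(fileext = ".sam")
  write_simulation(sim, samf)
  out <- tempfile(fileext = ".sam")
  report <- run_pipeline(list(input = samf, out = out, bed = bed, ...))
  list(report = report, out = out, input = samf)
}

# alignment lines of a SAM file (header dropped)
aln_lines <- function(path) {
  l <- readLines(path)
  l[!startsWith(l, "@")]
}

# qnames marked 0x400 in an exported SAM
marked_qnames <- function(path) {
  b <- read_sam(path)$batch
  unique(b$qname[bitwAnd(b$flag, 1024L) > 0L])
}
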
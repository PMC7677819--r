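# colsam

Columnar in-memory SAM and a shared-object data plane for variant-calling
pre-processing.

## The problem

The pre-processing half of a GATK-style short-read workflow — coordinate
sorting, duplicate marking, base-quality updates restricted to target
intervals — is conventionally run as a chain of independent tools that each
decompress, re-parse and re-write row-oriented SAM/BAM files between
stages. Most of that work is I/O and (de)serialisation, not analysis, and
each stage touches only a handful of the twelve SAM fields it reads.

`colsam` keeps alignment records in a columnar layout instead — one column
per SAM field (the 11 mandatory fields plus one verbatim `tags` column) —
partitioned by chromosome. Stages exchange data exclusively through a
shared pool of named, **sealed, immutable** objects encoded as
memory-mappable Arrow IPC files, so independent worker processes can read
the same columns without re-parsing or copying. Stage outputs that touch a
single field are stored as *delta columns* rather than rewritten batches:

- duplicate marking emits a replacement **FLAG** column per chunk
  (`flag_delta`), differing from the source only in bit `0x400`;
- interval-restricted quality updates emit a **QUAL + INDEX** column pair
  (`qual_index_delta`), where INDEX maps each surviving row back to its
  0-based source row, so downstream consumers gather reads by index as an
  alternative to re-evaluating intervals.

Each pipeline stage sees a fixed field projection (`stage_view`): duplicate
marking reads {QNAME, FLAG, RNAME, POS, CIGAR, RNEXT}; base-quality
recalibration reads {RNAME, POS, MAPQ, CIGAR, SEQ, QUAL} plus the merged
FLAG; variant calling reads eight fields including the replacement QUAL and
INDEX.

Duplicate marking groups candidate reads by **unclipped 5' end and strand**
(`unclipped_5p`: POS corrected for soft/hard clips, on the read's
sequencing strand; pairs by the canonical two-end key so both mates agree
independently). In each group the highest-scoring member survives
(default score: sum of base qualities with Phred ≥ 15) and the rest get
FLAG bit `0x400`. Chromosome partitions larger than a byte bound
(default 2 GiB) are split into chunks at position boundaries with a
padding overlap, and per-chunk results are provably identical to the
unchunked run.

A bundled simulator (`simulate_reads`) generates SAM with planted
duplicate groups and a machine-readable truth table, so the whole pipeline
is testable without any external dataset.

## Worked example

```r
library(colsam)

sim <- simulate_reads(n_fragments = 2000, dup_groups = 150, seed = 4)
write_simulation(sim, "example.sam", "truth.tsv")

rep <- run_pipeline(list(input = "example.sam", out = "out.sam"))
#> [colsam] ingest     1.03s  3983 reads, 26 partitions
#> [colsam] sort       0.46s  26 chromosomes
#> [colsam] markdup    1.20s  558 duplicates
#> [colsam] export     0.35s  3983 reads -> out.sam

rep$n_ingested     # 3983  reads parsed into the columnar model
rep$n_duplicates   # 558   rows whose FLAG gained bit 0x400
rep$n_exported     # 3983  rows written back out (marking never drops reads)
head(rep$inventory, 3)
#>                key payload_type byte_size
#> 1 flagdelta/chr1/0    flagdelta      1922
#> 2 flagdelta/chr2/0    flagdelta      2098
#> 3 flagdelta/chr3/0    flagdelta      1962
```

The 3983 simulated reads (2000 background templates, most of them paired,
plus 150 planted duplicate groups) land in 26 partitions — the 25
references of the human-style dictionary plus the reserved `*` partition
for unmapped reads. 558 rows are marked: every planted group of size *g*
contributes *g − 1* marked templates (both mates of a losing pair are
marked), which you can verify against `truth.tsv`. The export is the
coordinate-sorted input with only FLAG bits changed.

The same pipeline is scriptable from a shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "colsam", package = "colsam"))')
$CLI simulate --out example.sam --n-fragments 2000 --seed 4
$CLI pipeline --in example.sam --out out.sam --workers 8 --report report.json
$CLI store ls --store /path/to/store
```

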
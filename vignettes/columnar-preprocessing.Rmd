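---
title: "Columnar SAM pre-processing: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Columnar SAM pre-processing: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colsam)
```

## The data model

A `read_batch` is a twelve-column table: the eleven mandatory SAM fields
plus a `tags` column that keeps the optional fields as one verbatim,
tab-joined string. Two considerations fix this schema. First, every
pre-processing stage needs columnar access only to mandatory fields, so
optional tags never pay a parsing cost they do not earn (the one exception,
the mate-CIGAR `MC` tag, is extracted lazily inside duplicate marking).
Second, a verbatim `tags` column is what makes SAM export byte-identical to
the input — no re-typing, no re-ordering, no float re-formatting. SEQ and
QUAL are likewise stored as SAM text strings (Phred+33), decoded to
integers only where scoring needs them.

Reads are partitioned by RNAME into per-chromosome partitions; a reserved
`*` partition collects unmapped reads, bypasses sorting and marking, and is
re-appended at export so the pipeline is lossless. A partition is an
ordered list of chunks; each chunk owns a contiguous block of
coordinate-sorted rows and may carry read-only padding rows from its
neighbours (below).

All inter-stage traffic goes through an object store: a directory of
uncompressed Arrow IPC (Feather v2) files, one per object, plus per-object
JSON manifest entries. `put` writes the payload to a temporary file,
renames it into place and only then writes the manifest entry, so a
concurrent reader in another OS process observes either a sealed object or
none — create/seal/get/delete semantics without a daemon and without file
locking. Objects are immutable once sealed; stage outputs go to a fresh
namespace (`aligned` → `sorted` → `flagdelta` → `qualindex`) and the input
generation is dropped atomically afterwards (configurable, because keeping
the pre-sort generation is occasionally useful for debugging).

## Sorting

Within a chromosome the sort key is the leftmost mapping position alone,
and the sort is stable: reads at equal positions keep their input order.
A stable single-key sort keeps the independent test oracle trivial
(sort `(pos, input rank)`) and matches what coordinate order means to
downstream consumers; adding qname/flag tie-breaks would change nothing
semantically but would couple the output to fields no consumer reads at
this stage. Reads with `pos == 0` inside a named chromosome (rare, but
legal in aligner output) sort first, since they precede every positive
position numerically.

Sorting happens before chunking: chunk boundaries are defined on sorted
positions, so each chromosome is sorted whole and then split.

## Chunking and the padding window

Partitions whose estimated size exceeds `max_bytes` (default 2 GiB — the
scale at which a single chromosome of a whole-genome run stops being a
convenient unit) are split into chunks. Sizes are *estimated*, not
measured: `approx_bytes` counts value bytes plus 4-byte offsets per string
column and 4 bytes per integer, which is platform-independent and makes
chunk boundaries reproducible everywhere.

Two rules make chunked processing equal serial processing:

1. **Cut points fall only between distinct positions.** A run of reads at
   one position is never torn apart; if a single position group alone
   exceeds `max_bytes` it becomes one oversized chunk and a warning is
   emitted (the alternative — splitting the group — would make duplicate
   marking boundary-dependent).
2. **Padding.** Each chunk carries read-only copies of neighbouring rows
   whose position lies within `pad_bp` (default 1000 bp) of the cut.
   Padding rows participate in duplicate grouping and scoring but receive
   no output flags — the chunk that owns them decides them. Any duplicate
   group spans at most (read reference span + clip) base pairs around its
   5' anchor, so whenever `pad_bp` is at least that span, every chunk sees
   every group it must decide completely, and chunked output is identical
   to unchunked output. The default of 1000 bp covers short-read
   geometries with a wide margin; tests exercise multi-chunk paths with
   `max_bytes` of a few hundred bytes, which is the same code path at desk
   scale.

## Duplicate marking

Candidates are primary, mapped alignments (not secondary `0x100`, not
supplementary `0x800`). The grouping coordinate is the unclipped 5' end:
forward reads use `POS −` leading S/H lengths; reverse reads use the
rightmost reference position plus trailing S/H lengths. Paired candidates
build a canonical two-end key — the lexicographically smaller
(chromosome, end, strand) triple first — so both mates, and both members
of a duplicate pair, compute the same key with no communication. The mate's
unclipped end comes from the `MC` tag when present; otherwise PNEXT is used
uncorrected and the fallback is counted (`mc_missing`), since without the
mate CIGAR no clip correction is possible in per-chromosome processing.

Within a key group the survivor is the highest-scoring entity; for pairs
the entity score is the sum of both mates' scores. Two scoring strategies
are provided: `sum_of_base_qualities` (default; Phred values ≥ 15 summed,
the convention of the standard marking tool) and `total_mapped_length`
(query bases in M/=/X). Ties break by (score descending, qname ascending) —
deterministic, so re-runs and worker counts cannot change output. An
unpaired read whose end coincides with any paired read's end is always
marked (a fragment never outranks a pair, regardless of score).

One subtlety is worth spelling out: a pair's two ends can be separated by
the full insert length, far beyond any reasonable `pad_bp`, so computing
pair scores inside a chunk would make results depend on where cuts fall.
`mark_duplicates_all` therefore computes per-qname pair scores over the
whole partition first and hands the map to every chunk. Group membership
itself is local (all rows sharing an end sit within clip distance of each
other, inside the padding window), so this one partition-level pass is the
only non-chunk-local computation in the pipeline.

Marking writes a FLAG delta per chunk: a replacement FLAG column over the
chunk's owned rows, differing from the source only in bit `0x400`. Reads
are never dropped.

## Interval filtering, INDEX and resolution

Target-interval filtering converts BED (0-based, half-open; overlapping
and adjacent intervals merged on load, since only membership matters
downstream) to 1-based inclusive coordinates and keeps a read iff its
reference span `[POS, POS + reference-consumed(CIGAR) − 1]` overlaps an
interval on its chromosome — span overlap, not start containment, which is
the semantics target-restricted callers use. Reads with CIGAR `*` or
`POS 0` never survive; consequently, when filtering is active the unmapped
partition is not exported, and the run report satisfies
`ingested = exported + filtered out`.

The surviving rows get a replacement QUAL (any per-base Phred→Phred
mapping; the recalibration model itself is deliberately out of scope — the
hook accepts an externally computed mapping, a constant cap, or the
identity) and an INDEX column of 0-based source-row positions, strictly
increasing. INDEX is relative to the *owned rows of its chunk*, with the
(chromosome, ordinal) carried by the object key, so chunks remain
independently processable. `resolve_reads` is, by construction, exactly
`slice_rows(source, INDEX)` with FLAG and QUAL substituted — the test
suite asserts this compositional identity column by column, and that
resolution preserves coordinate order.

## The simulator: what it emulates, what it does not

`simulate_reads` emulates the *combinatorial* structure the pipeline must
get right, not sequencing physics: multi-chromosome placement over a
25-reference human-style dictionary, paired and single-end templates,
soft-clipped members of duplicate groups that share an unclipped end while
differing in POS (the case clip correction exists for), occasional
cross-chromosome mates, unmapped reads, and a uniformly shuffled record
order. Every planted group designates its survivor by giving one member
maximal base qualities (Phred 40) and the others per-base qualities capped
strictly below, so truth tables are independent of tie-breaking. All 5'
ends of distinct templates are drawn from a per-(chromosome, strand)
registry without collision, so no accidental duplicate groups arise.

It does **not** model base-calling error profiles, quality-by-cycle
structure, optical duplicate geometry, alignment artefacts, or realistic
insert-size distributions (inserts are uniform in 250–350 bp). Passing
tests therefore demonstrate that the data plane's transformations are
exact — ordering, grouping, flag arithmetic, index bookkeeping,
round-trips — on structurally realistic input; they say nothing about
alignment quality or recalibration accuracy on real data, which are
upstream and downstream of this package's scope.

Defaults: read length 100 bp, 60% paired, clip probability 0.3 (max
10 bp), 2% unmapped, 1% cross-chromosome mates, background qualities
Phred 20–39 — ordinary short-read exome-like values.

## Numerical and degenerate-input choices

- `approx_bytes` is computed, never measured, for reproducible chunking.
- Quality transforms are validated against the full Phred domain 0–93
  before use; `"*"` (unavailable) qualities pass through untouched.
- Empty partitions, empty batches, empty interval sets, header-only SAM
  and zero-row chunks are all legal and covered by tests.
- Validation (`validate_batch`) returns a violation table rather than
  throwing, so ingest tooling can report every problem at once.
- The BED reader merges adjacent intervals (end == next start): membership
  downstream cannot distinguish them, and a canonical disjoint set makes
  the overlap test and its oracle unambiguous.

## Validation problem sizes

The package validates itself at sizes chosen to finish in seconds on one
CPU while exercising every multi-chunk and multi-worker path: ~50,000-read
round-trip and sort checks across all 25 references, duplicate-truth runs
with 200 planted groups (sizes 2–5, clip probability 0.3), an O(n²)
brute-force marking oracle on ~2,000-read runs, worker counts 1 vs 8, and
chunking at `max_bytes` = 1 KB against the unchunked reference. The
acceptance script (`scripts/acceptance.R`) recomputes all of these from
fresh simulations under a caller-supplied seed.

## Known limitations

- SAM text only (no BAM/CRAM); the design premise is precisely to avoid
  the compressed row format between stages. No gzip transparency.
- Coordinate order only; query-name sorting is out of scope.
- No optical-duplicate distance classification and no library-aware (LB)
  grouping; all duplicates are plain duplicates.
- The recalibration *model* is not implemented — only its data plane
  (projection, interval filter, QUAL/INDEX deltas, export) — so external
  tools supply the actual quality mapping.
- Cross-chromosome pair scores use only the locally visible mate; exact
  two-sided scores for such pairs would require inter-partition
  communication that per-chromosome processing deliberately avoids.
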
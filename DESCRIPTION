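Package: colsam
Title: Columnar In-Memory SAM Representation and Pre-Processing Data Plane
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A columnar, Arrow-backed in-memory representation of SAM
    alignment records and the pre-processing stages of a GATK-style
    variant-calling workflow built on top of it: per-chromosome
    partitioning with size-bounded chunking, coordinate sorting,
    duplicate marking emitted as a FLAG delta column, BED-interval
    filtering with an INDEX back-mapping column, per-stage field
    projections, and byte-faithful SAM export. Stages exchange data
    exclusively through a shared pool of named, sealed, immutable
    objects encoded as memory-mappable Arrow IPC files, so independent
    worker processes can run chromosome-parallel with results identical
    to serial execution. A bundled synthetic-read simulator plants
    duplicate groups with a machine-readable truth table so the whole
    pipeline is testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    arrow,
    jsonlite,
    yaml,
    IRanges,
    parallel,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
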
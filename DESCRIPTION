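Package: concatemeR
Title: Consensus eccDNA Calling from Rolling-Circle-Amplified Nanopore Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reconstructs extrachromosomal circular DNA (eccDNA) from the
    tandem sub-read alignments of rolling-circle-amplified (RCA) long reads.
    Takes PAF alignments with base-level cs difference strings, clusters
    sub-read loci with a bounded start/end offset, verifies cyclic order and
    strand concordance, votes and threads fragment boundaries, keeps circles
    covered by at least two full passes, calls per-circle sequence variants
    from the stacked passes and emits variant-aware full-length consensus
    sequences. A catalog layer deduplicates circles into unique eccDNAs and
    computes event-count fractions, per-base genome coverage, fragment-count
    classes, inter-chromosomal pairings and the nucleosomal size-periodicity
    statistic. An RCA concatemer simulator generates ground-truthed
    references, reads and alignments so the whole pipeline is verifiable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
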
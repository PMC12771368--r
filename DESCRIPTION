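Package: isoforge
Title: Full-Length Transcript Isoform Reconstruction from Long cDNA Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs full-length transcript isoforms (transcription start
    region, splice chain, polyadenylation region) from long cDNA reads using
    biological-replicate concordance, peak calling on strand-specific read-end
    coverage, and splice-site correction against short-read junction sets.
    Includes optional downsampling of highly expressed genes or regions, a
    read simulator for fixture generation, and a transcript-level benchmarking
    harness with points- and peaks-mode precision/recall/F1 evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    rtracklayer,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
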
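Package: longcirc
Title: Back-Splice Junction Detection and Splicing Characterization of
    Circular RNAs from Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects back-splice junctions (BSJs) in split long-read
    alignments (PSL), assembles and end-corrects full-length circRNA calls,
    and characterizes circRNA-specific splicing: intron retention, novel and
    cryptic exons, microexons, alternative exon usage, reading-frame
    consequences, and cross-assembly conservation of BSJ coordinates via
    chain-file liftover of 20-bp end anchors. Includes a deterministic
    simulator that generates toy genomes, gene models, circRNA isoforms and
    once-nicked or concatemeric long reads with ground truth, so every stage
    of the pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
biocViews: Transcriptomics, Sequencing, LongRead, AlternativeSplicing
Config/testthat/edition: 3
RoxygenNote: 7.3.3
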
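Package: alienscan
Title: Identification of Alien-Chromosome Transcripts in Addition Lines
    by Identical-by-Descent Sequence Matching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects transcripts expressed from a donor ("alien") chromosome
    in a chromosome-addition backcross line by comparing two assembled
    transcriptome libraries for contigs that are identical by descent.
    Implements maximal exact match scanning with Karlin-Altschul E-value
    scoring, zero-mismatch overlap-alignment verification, transcriptome
    uniqueness screening, in-silico PCR marker design and genotype-panel
    screening with CAPS restriction-digest polymorphism detection and a
    linkage rule engine, plus Fisher's exact test comparison of annotation
    term counts between libraries with false discovery rate control. A
    synthetic-data generator emulates the donor / recurrent-parent /
    addition-line design so every stage can be exercised and benchmarked
    against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'alienscan-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'libcompare.R'
    'markers.R'
    'matchscan.R'
    'pairverify.R'
    'pipeline.R'
    'seqio.R'
    'synthdata.R'
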
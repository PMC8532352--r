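Package: txsv
Title: Detection of Novel Transcribed Structural and Splice Variants from RNA-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects novel transcribed structural variants (fusions, indels,
    internal and partial tandem duplications, inversions) and novel splice
    variants (extended, novel and truncated exons, skipped exons, retained
    introns) from RNA-seq by comparing one case sample against a panel of
    controls. De-novo-assembled contigs are quantified jointly with the
    reference transcriptome by k-mer pseudo-alignment into equivalence
    classes; equivalence classes composed solely of assembled contigs are
    tested for over-expression in the case with a fixed-dispersion negative
    binomial likelihood-ratio test, and contigs from significant classes are
    classified from their spliced genome alignments against the reference
    annotation. Ships a 15-class variant simulator, a paired-end read
    simulator and benchmark evaluation utilities so the whole method can be
    exercised on synthetic genomes without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    ShortRead,
    rtracklayer,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    generics,
    ggplot2,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    optparse,
    jsonlite
Config/testthat/edition: 3
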
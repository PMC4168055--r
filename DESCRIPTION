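Package: srnapipe
Title: Small RNA Classification, Differential Abundance and
    siRNA-Methylation Integration for Plant-Microbe Association Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for plant small-RNA sequencing libraries
    from two-condition experiments (e.g. mock versus bacteria-inoculated
    maize seedlings). Trims 3' adapters and filters reads into
    non-redundant tag libraries; profiles conserved mature miRNAs by
    mismatch-tolerant matching and collapses them to families; discovers
    novel class-I miRNAs by genome mapping, locus clustering, hairpin
    folding with a nearest-neighbor energy model, miRNA/miRNA* duplex
    validation and a dinucleotide-shuffle randomization test; computes
    RPM-normalized log2 fold changes with two-sided Fisher exact tests
    and Bonferroni correction; predicts miRNA targets by seed-weighted
    complementarity scoring; classifies siRNA candidates against repeat
    and coding-sequence references with best-hit mismatch alignment;
    calls positional siRNA hotspots on coding sequences and co-locates
    them with cytosine-methylation context levels and transcript
    coverage. A synthetic-data module generates genomes, references,
    read libraries and epigenomic tracks with fully recorded planted
    truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
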
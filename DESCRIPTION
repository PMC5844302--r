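Package: dmrkit
Title: Whole-Genome Bisulfite Sequencing Methylome Analysis with Planted-Truth Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-alignment analysis of whole-genome bisulfite sequencing
    (WGBS) methylomes: per-read-position M-bias profiling with an adaptive
    trim-range rule, polymorphism-aware genomic-context validation of CpG
    sites from strand-split base pileups, depth-filtered CpG methylation
    calling with bisulfite-conversion estimation from unmethylated spike-in
    controls, differentially-methylated-region (DMR) detection between two
    groups using a Beta-posterior credible methylation difference with a
    minimum nominal difference filter, gene-model and CpG-island
    shore/shelf annotation, and overlap-enrichment testing against
    length-matched shuffled null regions with a two-proportion Z-test.
    A synthetic WGBS data generator with planted focal effects,
    CpG-destroying polymorphisms, read-end bias artifacts and an
    unmethylated spike-in contig makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
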
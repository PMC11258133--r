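Package: teloscope
Title: Telomeric Repeat Discovery, K-Mer Genome Profiling and Assembly QC
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers telomeric tandem-repeat motifs (including novel units)
    directly from short sequencing reads, estimates genome size and
    heterozygosity from k-mer multiplicity spectra, and computes
    assembly-level quality summaries: contig statistics, contig-end telomere
    scans, 100-kb binned density tracks, repeat-versus-depth comparisons,
    structural-variant length spectra and Circos-compatible track exports.
    Includes a synthetic diploid genome and read simulator with recorded
    ground truth so that every stage is verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
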
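Package: strdecomp
Title: Alignment-Free Comparison of Genomic Regions by k-mer Spectrum
    Correlation Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for alignment-free comparison of genomic region classes
    (genes, exons, CDS, introns, intergenic regions) via k-mer spectra.
    Computes Pearson correlations between spectra, subtracts Markov-model
    reference ensembles, and decomposes correlations into the contributions
    of named word sets, in particular short tandem repeat (STR) words of
    unit length 1-2, extended base-code families (polyW, homoR, ...) and
    G+C-content bins. Includes mismatch-tolerant (Hamming distance one)
    contribution analysis, strand-pattern classification (inverse
    complement versus shift), a deviation-pattern rule engine for
    single-base mismatches inside STR tracts, and a synthetic genome
    generator with planted repeat tracts for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    Rcpp,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    pheatmap,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
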
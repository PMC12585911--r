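Package: repairscape
Title: Genome-Wide Cartography of UV Damage Formation and Nucleotide Excision Repair
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building genome-wide maps of UV-induced DNA damage and
    nucleotide excision repair from Damage-seq and XR-seq alignments. Implements
    the post-alignment read filters and damage-site inference used for
    single-nucleotide damage maps, a dinucleotide-composition-preserving
    background read simulator, strand-specific gene and peak/dyad-centred binned
    profiles with the mock/naked/simulation normalization chain, expression- and
    chromatin-stratified strand-asymmetry statistics, and quantification of
    nucleosome-scale periodicity by Fourier power spectra, signal-to-noise
    ratios and permutation tests. A synthetic-data module generates toy genomes,
    annotations and reads with known ground truth so every stage has a recovery
    test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
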
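Package: grasswgd
Title: Whole-Genome Duplication Detection, Ks Dating and Duplicate
    Expression Fates in Grass Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for the comparative-genomic inference chain
    used to characterise a lineage-specific whole-genome duplication (WGD)
    in a grass genome and its consequences under salt stress: k-mer
    histogram genome-size estimation, homolog detection and collinear
    block chaining, dotplot ortholog/outparalog classification and
    syntenic-multiplicity inference, NG86 Ka/Ks estimation with
    mixture-based Ks peak detection and proportional age calibration,
    ancestral-karyotype chromosome painting with fusion detection, and
    negative-binomial differential expression with classification of
    duplicate-pair expression fates (patterns I-IV). A synthetic-data
    module generates gene-order genomes with planted WGDs, codon pairs at
    controlled synonymous divergence, k-mer depth histograms and
    RNA-seq counts with planted effects, so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    mclust,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    DESeq2
Config/testthat/edition: 3
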
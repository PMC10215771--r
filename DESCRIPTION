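Package: rohscan
Title: Runs of Homozygosity, Genomic Inbreeding and ROH Islands from
    SNP Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects runs of homozygosity (ROH) in diploid SNP genotype
    panels with a PLINK-style sliding-window scan, stratifies them into
    length classes, and estimates per-individual genomic inbreeding
    coefficients from ROH coverage (F_ROH), excess homozygosity (F_HOM)
    and the diagonal of the VanRaden genomic relationship matrix (F_GRM).
    Also computes standard genetic-diversity indices (observed and
    expected heterozygosity, polymorphism rate, minor-allele-frequency
    spectrum, nucleotide diversity) and linkage-disequilibrium decay,
    identifies ROH islands as top-percentile ROH-incidence regions with
    gene annotation, and ships a pedigree gene-dropping simulator that
    produces genotype panels with known autozygous segments and pedigree
    inbreeding coefficients for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
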
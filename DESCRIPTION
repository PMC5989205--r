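Package: hapdose
Title: Direct Maternal Haplotype Phasing and Relative Haplotype Dosage
    Analysis for Noninvasive Prenatal Diagnosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for noninvasive prenatal diagnosis (NIPD) of X-linked
    recessive disease from targeted linked-read sequencing of a carrier
    mother and shallow sequencing of her plasma cell-free DNA.  Implements
    barcode-based phasing of the mutant-linked (HapA) and wild-type-linked
    (HapB) maternal haplotypes, linkage of large deletion and duplication
    mutations to a phased haplotype, and relative haplotype dosage (RHDO)
    analysis of plasma allelic depths with PELT changepoint detection and
    recombination adjustment.  Ships a linked-read and plasma cfDNA
    simulator so the whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
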
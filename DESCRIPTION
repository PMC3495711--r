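Package: ASPrimer
Title: Rule-Based Allele-Specific PCR Primer Design for SNP Genotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Designs allele-specific PCR (AS-PCR) primer pairs for biallelic
    SNPs by placing the allele-discriminating base at the primer 3' terminus
    and introducing a single artificial mismatch at the 2nd, 3rd or 4th base
    from the 3' end. The mismatch site and substituted base are selected
    deterministically from empirically derived rule tables of polymorphism
    rates by compressed SNP type, mismatch site and mismatch class, yielding
    one canonical best primer per SNP. Includes nearest-neighbor melting
    temperature calculation, SNP spectrum and rule-table statistics with
    Wilson confidence intervals, primer-table auditing, a synthetic-data
    generator for references, SNP panels and primer-validation outcomes, and
    FASTA/VCF/TSV/BED input-output with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    optparse
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
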
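Package: kinscan
Title: Window-Based IBD Classification, Parentage Validation and
    Haplotype-Sharing Scans for SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pedigree reconstruction and gene-flow analysis for diploid
    biallelic SNP panels, as used in germplasm collections of clonally
    propagated crops. Classifies genomic windows of non-repetitive
    sequence as IBD0/IBD1/IBD2 for every pair of accessions, calls
    parent-offspring and clone relationships from genome-wide IBD
    summaries, validates complete parent-offspring trios with an
    exhaustive Mendelian compatibility table and a model of the
    background inconsistency rate, detects full siblings, assembles a
    typed kinship network, scans for haplotype sharing with a homozygous
    reference accession to call carrier dosage and per-population
    haplotype frequencies, and groups accessions by ancestry
    coefficients. Includes a forward pedigree simulator with a
    genotyping-error model that reproduces the data structure these
    methods assume, with a machine-readable truth set for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
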
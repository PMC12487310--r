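Package: panelgwas
Title: Targeted SNP-Panel QC, Imputation, Translocation Scanning and
    Mixed-Model GWAS for Inbred Crop Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis toolkit for custom targeted
    genotyping-by-sequencing SNP panels in selfing crops such as winter
    wheat. Covers panel-design quality screens (flank GC content,
    exact-match uniqueness, probe feasibility), the call-rate /
    heterozygosity / minor-allele-frequency marker filter cascade,
    LD-kNNi genotype imputation, detection of alien chromosome
    translocations from missing-call structure, population-structure
    inference (centered-IBS kinship, PCA, neighbor-joining trees,
    admixture EM with Evanno delta-K model selection), and mixed
    linear model association mapping with SimpleM effective-test
    Bonferroni correction. Includes a seed-deterministic synthetic-data
    generator emulating an admixed 200-accession panel so every stage is
    testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    phangorn,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    cluster,
    withr
Config/testthat/edition: 3
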
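Package: accdiv
Title: Accession-Level SNP Diversity, Structure and Ascertainment-Bias Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-genetic analysis of diploid biallelic SNP panels
    genotyped on genebank accessions (multiple individuals per seed lot).
    Provides quality-control filtering of markers, individuals and
    accessions; allele-frequency and diversity statistics (Na, Ho, He, F)
    within accessions and pooled over groups; hierarchical AMOVA with
    permutation tests, pairwise Phi-st and Nei's standard genetic distance;
    Mantel tests and diversity-versus-geography regressions; principal
    component analysis of accession allele frequencies and individual
    genotypes with a within-accession PC-dispersion statistic and
    near-identical-individual detection; in-silico pooling of accessions
    under a major-allele-frequency cutoff; merging of mapped neighbouring
    SNPs into haplotype loci via an EM frequency estimator as a diagnostic
    for SNP ascertainment bias; and a Balding-Nichols hierarchical
    simulator producing panels with known ground truth for method
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan,
    vcfR
Config/testthat/edition: 3
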
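Package: emmerorigins
Title: Allele Sharing, Diversity and Association Analysis for Tetraploid Wheat Genotyping Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-SNP-calling population genetics for genotyping-by-sequencing
    panels of wild and domesticated tetraploid wheats. Simulates synthetic
    genotype cohorts with known ground truth (Balding-Nichols drift, admixture,
    domestication bottleneck, selfing, missingness and read depth), reads and
    filters multi-sample VCFs, computes diversity and differentiation
    statistics (nucleotide diversity, Tajima's D, Weir-Cockerham FST),
    infers structure (genotype PCA, VanRaden kinship, identity-by-state
    distances, neighbour-joining trees), classifies alleles by presence
    across three population groups with fixed-allele frequency differentials,
    and runs a mixed-linear-model genome-wide association scan on the binary
    domestication phenotype with Bonferroni thresholding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
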
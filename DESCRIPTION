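Package: indelpanel
Title: Forensic and Population-Genetic Analysis of Diallelic InDel Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistics and workflows for autosomal insertion/deletion (InDel)
    marker panels of the kind used in forensic genetics, such as the 30-locus
    Investigator DIPplex set. Computes per-locus forensic efficiency parameters
    (match probability, discrimination power, polymorphism information content,
    power of exclusion, typing paternity index, observed and unbiased expected
    heterozygosity) and their panel-wide combinations (cumulative match
    probability, combined power of exclusion); Hardy-Weinberg exact and
    chi-square tests with Bonferroni correction; pairwise linkage
    disequilibrium via EM haplotype-frequency estimation (D, D', r2);
    interpopulation differentiation tests (Fisher exact on allele counts,
    permutation tests on locus-wise theta); Nei's D_A distance and
    Weir-Cockerham F_st; neighbor-joining trees and classical multidimensional
    scaling; and a Gibbs-sampler admixture model for ancestry proportions.
    Includes simulators (Hardy-Weinberg, inbreeding, Balding-Nichols structure,
    admixture, two-locus haplotypes) so every stage can be exercised on data
    with known ground truth, plus readers and writers for delimited genotype
    tables, GenePop, PHYLIP distance matrices, and Newick trees.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
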
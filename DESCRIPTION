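Package: caninetraits
Title: Coat-Colour and Morphology Genetics for Dog Breed Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for working with panel genotypes at the twelve canine
    coat-colour and morphology genes (ASIP, MC1R, CBD103, TYRP1, MITF,
    PSMB7, RALY, FGF5, KRT71, T, BMP3 and the chromosome-10 ear-set
    marker). Assembles multi-allelic diploid genotypes from per-variant
    marker copy counts (including by-exclusion alleles and the cis
    a^y-a^t haplotype), predicts expressed phenotypes through the
    dominance hierarchies and epistatic interactions of the pigmentation
    pathway, estimates breed and subpopulation allele frequencies,
    screens breed-standard registries for "fault" alleles and computes
    random-mating fault-phenotype probabilities under Hardy-Weinberg
    with live-birth correction at homozygous-lethal loci, compares
    same-breed subpopulations with chi-square or Fisher exact tests
    under a Bonferroni scheme, and connects rare-allele carrier breeds
    through identity-by-descent haplotype-sharing networks. A seeded
    synthetic-cohort generator makes every pipeline stage testable
    without proprietary genotype data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
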
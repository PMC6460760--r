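Package: hzadmix
Title: Hybrid-Zone Admixture Analysis from Diagnostic SNP Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing diploid hybrid zones from biallelic SNP
    genotypes and phenotype scores. Selects diagnostic loci by the
    interspecies allele-frequency differential (delta), estimates
    per-individual maximum-likelihood hybrid indices and interspecific
    heterozygosity with rule-based hybrid-class assignment, fits per-locus
    genomic clines by multinomial regression on the genome-wide hybrid index
    and tests them against a neutral-admixture model by parametric bootstrap
    with Benjamini-Yekutieli and Benjamini-Hochberg false-discovery-rate
    control, computes pairwise Weir-Cockerham F_ST and genotype PCA, derives
    plumage hybrid indices and scaled plumage PCAs with geographic
    hybrid-zone profiling, and ships a Mendelian hybrid-zone simulator with
    known ground truth for every downstream stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    nnet,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
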
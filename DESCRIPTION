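Package: mqtlnet
Title: Co-Expression Module QTL Mapping and Integrative Regression for Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An integrative systems-genetics workflow for tumor expression and
    genotype cohorts. Builds a weighted gene co-expression network (soft-threshold
    adjacency, scale-free topology fit, topological overlap, module detection and
    eigengenes), maps module QTLs (mQTLs) by logistic regression with SNP allele
    counts as outcomes, calls hub genes from degree and betweenness centrality,
    scans SNP association with tumor stage under genomic control, and decomposes
    module gene significance into risk and protective mQTL components via
    stepwise-AIC regression. Includes genotype and expression quality control,
    k-nearest-neighbour imputation, hypergeometric gene-set enrichment,
    permutation protein-protein-interaction enrichment, replication-cohort
    differential-expression statistics, and a synthetic-cohort generator with
    planted modules and mQTL effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
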
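Package: giabank
Title: Genetically Inferred Ancestry and Phenome-Wide Association Pipelines for EHR-Linked Biobanks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully testable analytical pipeline for
    electronic-health-record linked biobank genotype data: variant and
    sample quality control with KING-robust kinship, reference-anchored
    principal-component analysis with per-ancestry K-nearest-neighbour
    assignment of genetically inferred ancestry (GIA), unsupervised
    admixture estimation by binomial-mixture EM, identity-by-descent
    sharing networks with InfoMap communities, ICD-to-phecode phenotype
    construction, and ancestry-aware association scans (GIA-phecode,
    admixture-phecode, per-ancestry GWAS, fixed-effects meta-analysis,
    and PheWAS).  A synthetic-data module generates reference panels,
    Dirichlet-admixed cohorts, demographics, encounters, and IBD
    segments with the statistical structure every downstream stage
    assumes, so the whole pipeline runs with no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    igraph,
    jsonlite,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    mclust,
    class,
    withr,
    optparse
Config/testthat/edition: 3
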
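Package: admixscan
Title: Admixture Mapping of Disease Risk in Three-Way Admixed Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for case-control admixture mapping in recently admixed
    populations with European, African, and Native American ancestry. The
    package simulates pulse-admixture local-ancestry tracts and matched
    genotype/phenotype data, summarises local-ancestry calls (depth QC,
    global-from-local proportions with bootstrap confidence intervals,
    tract lengths), scans local-ancestry dosages and SNP genotypes for
    disease association by logistic regression, computes a genome-wide
    family-wise significance threshold from the correlation structure of
    local ancestry via joint null simulation, fine-maps admixture peaks to
    tag SNPs by iterative conditional attenuation, and reproduces
    descriptive and nested risk-model epidemiology for case-control
    biobank data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    Rcpp,
    vcfR
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
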
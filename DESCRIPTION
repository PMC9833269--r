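Package: ldlprs
Title: LDL Cholesterol Polygenic Risk Scores for Familial Hypercholesterolemia Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the 12-SNP and 6-SNP LDL cholesterol polygenic risk
    scores with APOE epsilon-diplotype weighting from VCF or dosage-matrix
    genotypes, prepares treatment-corrected LDL-C and coronary artery calcium
    phenotypes, and runs the downstream association analyses (quantile
    stratification, LDL-C linear regression, age- and sex-adjusted logistic
    models for calcium burden, nonparametric group comparisons). Includes
    analytic expectation and variance oracles for the score under
    Hardy-Weinberg equilibrium and a synthetic cohort generator that emulates
    a control population and familial-hypercholesterolemia case groups from
    published allele and diplotype frequencies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    VariantAnnotation,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
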
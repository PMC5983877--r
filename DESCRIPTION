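Package: zimpute
Title: Summary Statistics Imputation for Genome-Wide Association Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Imputes association Z-statistics and standardized effect sizes of
    untyped variants from tag-SNV genome-wide association summary statistics and
    linkage-disequilibrium estimates taken from a reference genotype panel. The
    imputation is the conditional mean of a multivariate normal with shrinkage of
    the LD matrix, extended to account for variable per-variant sample size and
    sample-overlap (missingness) structure across tag variants. Also provides an
    imputation-quality metric adjusted for panel size and the effective number of
    tag variants, approximate conditional analysis with a candidate-locus scan
    against previously reported variants, a self-contained LD-block genotype and
    phenotype simulator with controllable missingness correlation, and evaluation
    utilities (RMSE, bias, slope, correlation, power and false-positive-rate
    curves with binomial errors).
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    MASS,
    stats,
    utils,
    vcfR,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
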
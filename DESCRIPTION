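Package: mppqtlx
Title: Multiparental Multi-Environment QTL Mapping with Environmental
    Covariate Sensitivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: QTL analysis for multiparental populations evaluated in
    multi-environment trials. Implements parental-allelic genome scans under
    an unstructured environmental variance-covariance model fitted by
    restricted maximum likelihood, simple and composite interval mapping with
    iterative cofactor selection, Li-Ji effective-number-of-tests thresholds,
    decomposition of QTL effects into main and QTL-by-environment interaction
    components, factorial regression of parental allelic effects on
    environmental covariates aggregated over developmental time windows, and
    projection of allelic effects onto environmental grids. Includes a
    backcross nested association mapping (BCNAM) simulator with known
    ground-truth QTL architecture, within-environment best linear unbiased
    estimates from plot data, and cross-specific variance components with
    broad-sense heritability.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
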
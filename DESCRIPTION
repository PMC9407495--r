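Package: peelpath
Title: Climate-Flavonoid-Peel-Color Inference for Fruit Provenance Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for inferring how annual climate factors shape
    flavonoid accumulation and CIELAB peel color in fruit peels sampled along
    an altitude gradient. Provides schema-validated sample tables with a
    bundled 26-provenance x 15-flavonoid quantification fixture, a
    linear-Gaussian synthetic-data generator with known causal structure,
    Pearson correlation screening with significance flags, multivariate
    chemotyping (PCA, hierarchical clustering with newick export, OPLS-DA),
    stepwise-screened path analysis with direct/indirect decomposition and
    decision coefficients, content-on-color regression, and covariance-based
    structural equation models fitted by maximum likelihood with RMSEA/AGFI
    fit indices and direct/indirect effect decomposition.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
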
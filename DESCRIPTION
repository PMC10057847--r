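Package: sensortune
Title: Precision Engineering of Genetic Sensor Dose-Response Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Tools for quantitative tuning of protein-based genetic sensors
    (such as the lac repressor, LacI) against dose-response specifications.
    Implements Bayesian Hill-equation fitting of calibrated cytometry
    dose-response curves, in silico selection of variants from large-scale
    genotype-phenotype landscapes by posterior probability of meeting
    multi-objective EC50/G-infinity/G0 specifications (with systematic-error
    correction of EC50), an interpretable latent genotype-phenotype model
    (low-dimensional linear embedding of one-hot genotypes composed with a
    smooth probabilistic surface) for forward prediction of novel mutation
    combinations, a thermodynamic MWC model of allosteric repression, a
    synthetic-landscape generator emulating deep-mutational-scanning data,
    and fold-accuracy evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    mgcv,
    rjags,
    coda,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
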
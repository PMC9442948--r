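Package: sirdesign
Title: Optimal Design and Power Analysis for Disease Transmission Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing disease transmission experiments that estimate
    the effects of a SNP (or any categorical factor such as vaccination status)
    on host susceptibility, infectivity and recoverability under an SIR model.
    Implements analytic precision formulas based on the Fisher information of
    the complete-data epidemic likelihood, optimisation of seeder fractions and
    genotype compositions across contact groups, a stochastic continuous-time
    simulator of group epidemics with genetic trait variation, and
    maximum-likelihood inference with observed-information standard errors for
    validating the analytic precision estimates against simulated data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
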
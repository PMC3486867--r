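Package: phlinkage
Title: Proton-Linkage Analysis of pH-Coupled Conformational Equilibria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Four-state thermodynamic linkage analysis connecting
    conformation-specific (microscopic) pKa values of a titratable residue
    to the apparent pKa of a pH-driven conformational transition, modelled
    on the nitrophorin 4 closed-to-open switch. Provides closed-form
    species populations, signal curves and apparent-pKa calculations; a
    coarse-grained Metropolis Monte Carlo simulator of the coupled
    protonation/conformation system emulating constant-pH molecular
    dynamics output; and estimators that recover microscopic pKa values
    from trajectory or titration data via Henderson-Hasselbalch inversion
    and binomial titration fits.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
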
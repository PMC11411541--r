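Package: vectorgc
Title: Vector Group-Contribution Prediction of PCP-SAFT Parameters for
    Dipolar Molecules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts pure-component PCP-SAFT parameters (segment number m,
    segment diameter sigma, dispersion energy eps/k, and the dipole parameter
    mu) for aliphatic, acyclic, nonassociating oxygenated and halogenated
    molecules directly from isomeric SMILES. Molecules are fragmented into
    first- and second-order groups and polar bonds; m, m*sigma^3 and m*eps
    are summed over group contributions, while the dipole parameter is the
    magnitude of a vector sum of bond dipole contributions oriented along an
    embedded, force-field-refined 3D conformer, so that molecular symmetry
    and cis/trans isomerism are resolved. Includes the full regression
    framework used to calibrate such group-contribution tables: a weighted
    logarithmic least-squares objective over vapor-pressure and liquid
    density data, bound-constrained simultaneous fitting of group and bond
    contributions, substance-level leave-one-out cross-validation with joint
    handling of cis/trans pairs, and MAPD reporting, over a pluggable
    property evaluator with an analytic surrogate for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineR,
    minpack.lm,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: OpenBabel (the 'obabel' executable on the PATH)
Config/testthat/edition: 3
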
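Package: metsom
Title: Fragmentation-Pattern Identification of Sirolimus Metabolites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structural elucidation of sirolimus (rapamycin) metabolites from
    high-resolution MS/MS fragmentation patterns. Provides exact monoisotopic
    mass and adduct-ion arithmetic with ppm-error matching, a sodiated
    fragment library with carbon-coverage semantics and a fragmentation tree,
    a forward model from modification hypotheses to expected peak sets, and an
    inverse site-of-metabolism solver that localizes O-demethylation and
    hydroxylation sites from shifted, unshifted and diagnostic fragments.
    Also fits Michaelis-Menten formation kinetics of microsomal metabolites
    with bootstrap confidence intervals and intrinsic clearance, combines
    thermodynamic-cycle free energies to rank demethylation sites, ranks
    candidate sites from atom-to-heme-iron distance trajectories, and
    simulates QTOF-style spectra, kinetics datasets and distance trajectories
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
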
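Package: colikin
Title: Kinetic Modelling and Control Analysis of Escherichia coli Central
    Carbon and Energy Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to build, simulate and analyse kinetic (ODE) models of
    microbial central carbon and energy metabolism. Ships a synthetic
    reference instance of the Escherichia coli central carbon and energy
    network (glucose phosphotransferase system, glycolysis, pentose
    phosphate and Entner-Doudoroff pathways, TCA cycle and glyoxylate
    shunt, acetate metabolism, oxidative phosphorylation with an explicit
    proton-motive gating of the respiratory chain, nucleotide
    interconversion and a multiplicative growth reaction). Provides
    steady-state solving by damped Newton iteration with an
    integrate-to-steady-state fallback, metabolic control analysis by
    finite differences with summation-theorem validation, ensemble
    exploration of the kinetic solution space under random enzyme levels,
    uniform hit-and-run sampling of the stoichiometric flux polytope,
    solution-space boundary estimation, functional-coupling statistics
    (Spearman rank correlation and mutual information on equal-frequency
    bins), metabolite homeostasis summaries, and constrained weighted
    least-squares calibration by particle swarm optimization. Models are
    exchanged as SBML Level 3 (subset) or a plain-text parameter table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    boot,
    jsonlite,
    xml2,
    compiler,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
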
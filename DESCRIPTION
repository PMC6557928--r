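Package: SRCMkinetics
Title: Kinetic Modeling of Stickland-Reaction-Coupled Methanogenesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compartmental kinetic modeling of syntrophic amino-acid
    fermentation coupled to aceticlastic methanogenesis. Provides S4 classes
    for kinetic reaction networks with Michaelis-Menten and generalized
    mass-action rate laws across an acidogen / medium / methanogen
    three-compartment topology, deterministic stiff-ODE and Gibson-Bruck
    next-reaction stochastic time-course simulation, steady-state finding with
    eigenvalue stability analysis, metabolic control analysis (elasticities
    and flux control coefficients), flux-objective optimization of methane
    production under amino-acid substrate constraints, least-squares parameter
    estimation from time-course data, synthetic data generation (kinetic
    parameter tables, gelatin-hydrolysate feeds, noisy observations), and
    SBML Level 3 Version 1 interchange.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    deSolve,
    minpack.lm,
    pracma,
    yaml,
    jsonlite,
    xml2,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
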
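Package: cyanoflux
Title: Constraint-Based Analysis of Photon-Resolved Metabolism in
    Diazotrophic Cyanobacteria
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for constraint-based analysis of genome-scale metabolic
    models of oxygenic phototrophs with explicit photosystem I and II photon
    uptake reactions. Implements flux balance analysis and quadratic
    flux-norm minimization, flux variability analysis with
    required/optional/inactive classification, photon-resolved phenotypic
    phase planes with region-wise variability analysis and
    reductant-vs-energy limitation diagnosis, dark nitrogen-fixation
    energetics, estimation of growth- and non-growth-associated ATP
    requirements from batch photobioreactor data, mixed-integer quadratic
    integration of transcriptome and proteome evidence into flux states, and
    deletion scans that shrink central-metabolic flux spans. Includes SBML
    input/output, construction of biomass equations from measured
    macromolecular composition, and a fully synthetic toy phototroph network
    generator for testing and method development.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    quadprog,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'solvers.R'
    'gpr.R'
    'network-io.R'
    'sbml.R'
    'fba-core.R'
    'phototrophy.R'
    'energetics.R'
    'tpd-integration.R'
    'deletion-analysis.R'
    'synthetic-data.R'
    'workflow.R'
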
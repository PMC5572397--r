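Package: enzgem
Title: Enzyme-Constrained Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms constraint-based genome-scale metabolic models into
    enzyme-constrained models in which every catalyzed flux is bounded by the
    product of a turnover number and an enzyme abundance. Reversible reactions
    are split, isozymes receive arm reactions with pseudo-metabolites,
    complexes consume all subunits according to their stoichiometry, and
    promiscuous enzymes share one abundance across reactions. Turnover numbers
    are assigned by hierarchical matching against a local kinetics table with
    EC-number wildcards. Abundance limits come from a shared enzyme-mass pool,
    from absolute proteomics, or from a hybrid of both. Simulation recipes
    include flux balance analysis, parsimonious enzyme minimization,
    chemostat and batch protocols, knockouts, yield envelopes, flux
    variability analysis, flux control coefficients, and saturation fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2
Suggests:
    boot,
    withr,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
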
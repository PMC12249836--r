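Package: astroflux
Title: Constraint-Based Modeling of Astrocyte Metabolism Under Hypoxia and
    Acidosis with Proteomics Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Flux balance analysis (FBA) of astrocyte metabolic networks under
    hypoxic, acidic and combined stress conditions, and integration of the
    predicted flux shifts with differentially expressed proteins. Provides a
    constraint-based model container with SBML and JSON input, a
    bounded-variable simplex linear-programming engine with lexicographic
    multi-objective optimization, parsimonious FBA and flux variability
    analysis, reusable condition specifications (physiological uptake rates,
    oxygen restriction, buffering-capacity reduction), percent-change flux
    comparison with a robust-change threshold and enzyme attribution via
    gene-protein-reaction rules, a proteomics module (Welch tests,
    Benjamini-Hochberg adjustment, fold-change/significance filtering), an
    enzyme-reaction concordance table in the style of a split heatmap, and a
    fully synthetic test bed: a lumped astrocyte toy network with closed-form
    optima and a planted-effect proteomics generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
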
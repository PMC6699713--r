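Package: chemevo
Title: Eco-Evolutionary Chemostat Models of Cross-Feeding Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Consumer-resource chemostat models of microbial communities that
    degrade substrates along a catabolic pathway with cross-feeding. Species
    grow by Monod (or linear) kinetics on the substrates they metabolize,
    subject to a fixed total enzyme budget allocated across reactions, with an
    optional concave cost of generalism. Provides the coupled substrate/density
    ordinary differential equations, quantitative-genetic evolution of enzyme
    allocation by a constrained G-matrix, closed-form steady states and
    persistence/coexistence thresholds for linear pathways, and a replication
    harness that contrasts specialist against generalist packaging of the same
    enzymes, including an 8-species fermentation pathway modelled on
    polysaccharide breakdown in the gut.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
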
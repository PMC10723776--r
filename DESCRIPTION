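Package: agromap
Title: Combinatorial Plot Maps for Agroforestry Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Topological modelling of agroforestry plots with 2D combinatorial
    maps. Provides a dart-based kernel (beta1 permutation, beta2 involution,
    orbits, validation), an incremental builder that assembles a closed plot
    map from georeferenced polygons with an explicit outside face and
    hierarchical holes (trees embedded in understory strips), derivation of
    the dual map used to model interactions between plot elements, dynamic
    structure edits (crown growth across face borders, element planting and
    thinning), exact attributed pattern matching with metric constraints, a
    synthetic alley-cropping plot generator, JSON and GeoJSON input/output,
    DOT export, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    pracma,
    stats,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
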
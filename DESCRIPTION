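Package: granpart
Title: Granular Partitions and Integrated Granularity Frameworks for
    Part-Whole Hierarchies
Version: 0.1.0
Authors@R:
    person("Granpart", "Developers", email = "granpart@example.org",
           role = c("aut", "cre"))
Description: Tools for validating typed partonomies (part-whole hierarchies
    over material entities classified as objects, fiat object parts, or
    object aggregates) as granular partitions, building granularity trees
    and their cuts, sedimenting instance granularity to type granularity,
    constructing and integrating compositional, spatial, resolution and
    size granularity perspectives, assigning structural granularity values
    (fixed naturals on the compositional-object backbone, exact rational
    intervals elsewhere), and linting external granularity schemes against
    formal granularity principles. Includes deterministic generators for
    cumulative-constitutively organized synthetic partonomies, JSON and OBO
    import, DOT export, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
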
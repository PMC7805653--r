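Package: saen
Title: Shift-Aggregate-Extract Networks over Hierarchical Graph Decompositions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents collections of attributed graphs as multi-level
    part-of hierarchies (H-decompositions), learns per-level vector
    representations with a shift/aggregate/extract neural computation, and
    losslessly compresses the hierarchies before training by collapsing
    objects that provably share representations for every parameter value.
    Includes ego-graph and nested-ego-graph decomposers with
    Weisfeiler-Lehman vertex refinement, the domain-compression algorithm
    with averaging and representer pseudo-inverses, readers and writers for
    the standard multi-file graph-classification benchmark layout, a
    synthetic two-class graph generator, and a repeated stratified k-fold
    cross-validation driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'hdecomp.R'
    'decomposers.R'
    'saen.R'
    'compression.R'
    'data-io.R'
    'cv.R'
    'cli.R'
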
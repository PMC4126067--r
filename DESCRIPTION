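Package: ftumotifs
Title: Functional Tissue Units and Primary Tissue Motif Classification
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for representing and classifying functional tissue units
    (FTUs), cylindrical blocks of cells organised around a feeding capillary
    and bounded by the ~100 micrometre diffusion limit, through their primary
    tissue motifs (PTMs): the non-redundant sets of cell-type ontology terms
    an FTU contains. Provides OBO ontology loading and term semantic
    similarity (ancestor-overlap and information-content measures), exclusive
    best-match alignment and similarity scoring between motifs, hierarchical
    classification of motif collections with Newick export, set-theoretic
    motif relations, the maximal-volume FTU cylinder geometry under the
    diffusion constraint, and extraction of motifs from annotated 3D cell
    point clouds around capillary axes. Ships a worked five-tissue example
    (hepatic, cardiac, pulmonary, colonic, gastric) and seeded synthetic-data
    generators so that every component is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
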
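Package: ClanOverlaps
Title: Cross-Clan Overlap Analysis of Profile-HMM Domain Hits
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects sequence regions that match two or more protein families
    from different Pfam clans at a given E-value significance threshold,
    resolves the resulting overlapping domains with a winner-takes-all greedy
    assignment (or an E-value-based alternative), labels families by
    compositional-bias features of their seed members (coiled-coil,
    intrinsic disorder, transmembrane helices), and computes the summary
    statistics that identify families whose E-values appear miscalibrated:
    expected false-positive counts, cumulative overlap curves, label
    overrepresentation folds, residue-level bias proportions in overlap
    regions, and null2 bias-correction flags. Includes a seeded synthetic-data
    generator that plants overlap structure, heptad-like coiled-coil tracks
    and bias scores so the whole pipeline is testable without database-scale
    searches.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
biocViews: SequenceMatching, Alignment, HiddenMarkovModel, Annotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'methods.R'
    'assignment.R'
    'io.R'
    'labeling.R'
    'overlap.R'
    'statistics.R'
    'pipeline.R'
    'synthetic.R'
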
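Package: GradeScreen
Title: Weighted Multi-Criteria Drug-Likeness Grading and Target-Centric
    Screening Utilities
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for computational drug-repurposing pipelines built
    around a weighted seven-criterion drug-likeness score with A-F
    letter grading, together with the structure-based utilities such a
    pipeline needs: compound parsing, canonicalization and
    structure-based deduplication; physicochemical descriptors, QED,
    a synthetic-accessibility estimate and PAINS/BRENK structural-alert
    screening; docking-box construction from co-crystal ligand
    coordinates with RMSD redocking validation; distance-cutoff
    protein-ligand interaction typing; and a Z-score-weighted
    five-centrality composite for hub-gene ranking in protein-protein
    interaction networks. Seeded synthetic-data generators (compound
    libraries, toy complexes with planted contacts, scale-free networks
    with planted hubs) make every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    ChemmineR,
    ChemmineOB,
    bio3d,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
biocViews: Cheminformatics, Network, GraphAndNetwork, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
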
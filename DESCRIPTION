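Package: topotier
Title: Charge-Tiered Shape-Distribution Fingerprints for Molecular Topology Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Alignment-free comparison of molecular topologies via charge-tiered
    shape distributions. Atoms are partitioned into partial-charge tiers
    (default tripartite at +/- 0.1 e), the pairwise interatomic distance
    distribution of each tier is summarised by five moments, and molecules are
    compared by the Manhattan distance between the concatenated moment vectors.
    Includes PDB/MOL2/PQR ligand and binding-pocket extraction with the
    associated size and metal filters, an iterative partial-equalization
    (Gasteiger-type) partial-charge assigner, ranked similarity search with
    multi-conformer queries, reduced top-k dissimilarity matrices, and
    virtual-screening evaluation statistics (enrichment factors at top
    fractions, per-query ROC AUC over ligand groups), plus deterministic
    synthetic structure generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
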
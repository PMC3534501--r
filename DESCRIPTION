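Package: domaincut
Title: Structural Domain Assignment for Proteins by Average-Linkage
    Clustering
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Assigns structural domains to protein 3D structures (single
    chains or whole complexes) by average-linkage agglomerative clustering
    of either buried alpha-carbon positions or vector representations of
    secondary-structure elements, cutting the resulting dendrogram at the
    first sufficiently wide merge-height gap. Includes residue burial
    classification, secondary-structure element vectorisation from DSSP
    annotations, an evaluation toolkit (best-permutation overlap,
    correctness thresholds, per-class Matthews correlation, a random
    baseline), and a synthetic-structure generator for end-to-end testing
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
biocViews: StructuralBioinformatics, Clustering, Proteomics
RoxygenNote: 7.3.3
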
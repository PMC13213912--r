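Package: nestedtmap
Title: Nested Tree-Map Atlases of Very Large Molecule Libraries via
    Product Quantization and PQk-Means
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clustering and visualization framework for very large small-molecule
    libraries. Molecules are represented as 42-dimensional MQN (molecular quantum
    numbers) count fingerprints, compressed to compact 6-byte codes by product
    quantization, and clustered directly in code space with PQk-Means using
    lookup-table symmetric distances. Each cluster is summarized by the member
    closest to its centroid, and the library is rendered as a nested atlas: a
    primary tree-map (k-nearest-neighbour graph reduced to its minimum spanning
    tree) over cluster representatives in MQN space, with secondary tree-maps of
    cluster members organized by ECFP4/Tanimoto similarity. Includes cluster
    quality diagnostics (within/between-cluster distance sampling, pairwise
    distance heatmaps, descriptor dispersion statistics), a sharded streaming
    pipeline, and synthetic fixture generators. Molecular descriptors are
    computed with RDKit through a bundled batch interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
SystemRequirements: Python (>= 3.8) with rdkit, on PATH as 'python'
RoxygenNote: 7.3.3
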
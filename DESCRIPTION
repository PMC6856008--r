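Package: hcsmiR
Title: Phenotypic miRNA High-Content Screening Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
        role = c("aut", "cre"))
Description: Analysis pipeline for image-based high-content screening (HCS)
        of microRNA mimic libraries. Segments nuclei, cells and cytoplasm
        from multi-channel fluorescence fields, computes per-cell
        morphometric and intensity features (area, eccentricity, solidity,
        neighbour counts, percent intercellular contact, compartment median
        intensities), aggregates them into percent-change-versus-negative-
        control phenotypic profiles, clusters miRNAs into survival/EMT
        phenotype groups by hierarchical clustering, identifies group
        consensus predicted targets with opposite-group exclusion, tests
        pathway enrichment (hypergeometric and EASE variants), exports the
        miRNA-target-pathway regulatory network, and quantifies
        exclusion-zone migration. Ships a synthetic-data module generating
        every input with planted ground truth so the whole pipeline is
        testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    tiff,
    jsonlite,
    igraph,
    ape,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    pheatmap
Config/testthat/edition: 3
biocViews: CellBasedAssays, Software, Visualization, Network, Pathways
RoxygenNote: 7.3.3
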
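Package: cryptscape
Title: Spatial Analysis of Crypt-Associated Mucosal Microbiota from 3D Imaging
Version: 0.1.0
Authors@R:
    person("Crypt", "Scape", email = "maintainer@cryptscape.dev", role = c("aut", "cre"))
Description: Quantitative spatial analysis of the intestinal mucosal
    microbiota from multi-channel 3D fluorescence volumes: linear spectral
    unmixing, intensity-filter segmentation of bacterial aggregates,
    per-crypt taxon abundances and center-of-mass depths, distance-threshold
    spatial clustering of colonized crypts, Z-score/cosine hierarchical
    community typing with silhouette validation, nearest-neighbor analysis
    of community types, staining sensitivity/specificity metrics, probe-set
    selection, and the group-comparison statistics used downstream. Includes
    a fully seeded synthetic mucosa generator (jittered crypt lattice,
    seed-and-spread colonization, community-type archetypes, taxon depth
    stratification, spectral mixing, depth-dependent staining efficiency)
    that provides ground truth for every analysis step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    cluster,
    optparse
Config/testthat/edition: 3
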
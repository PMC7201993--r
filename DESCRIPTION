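Package: disconnectr
Title: Lesion-Based Structural Disconnection Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for lesion-based structural disconnection analysis in a
    common template space: voxelwise lesion and disconnection frequency maps,
    per-subject disconnectome probability maps derived from a panel of
    normative streamline sets, voxelwise group comparison via permutation GLM
    with a lesion-size covariate and threshold-free cluster enhancement (TFCE)
    with family-wise error correction, and atlas-overlap reports quantifying
    differentially disconnected tracts, subcortical structures and cortical
    networks. Includes a synthetic-data module that simulates lesion cohorts,
    normative tractogram panels and labeled atlases with optional planted
    group differences, so the whole pipeline is testable without any
    neuroimaging download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
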
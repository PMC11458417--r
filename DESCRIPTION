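Package: splitparc
Title: Split-Half Consensus Parcellation of Functional Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Derives stable functional network parcellations from
    multi-participant resting-state fMRI timeseries. Voxelwise connectivity
    patterns between a region-of-interest mask and a context mask are
    summarised as a voxel-by-voxel similarity matrix, thresholded into binary
    graphs over a grid of edge densities, and clustered with the two-level
    map-equation (InfoMap) algorithm separately in random split-halves of the
    cohort. Only network distinctions that replicate across the halves
    (Dice overlap and minimum-volume criteria) over repeated random splits are
    retained, via an agreement matrix and a consensus rule. Final network
    labels are assigned to every brain voxel by winner-take-all correlation
    of its connectivity fingerprint with each network's average pattern,
    with nearest-neighbour filling of small unlabeled patches. Includes a
    planted-network synthetic data generator for end-to-end validation,
    agreement-curve diagnostics for threshold selection, and a recursive
    focused-parcellation mode for finer-grained maps within a parcel.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    igraph,
    jsonlite,
    mclust,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
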
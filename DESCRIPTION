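Package: cortmorph
Title: 3D Micro-CT Morphometry of Cortical Bone
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Digital morphometry of cortical bone from high-resolution 3D
    micro-CT volumes. Segments mineralized matrix, vessel-pore canals and
    osteocyte lacunae; computes gross morphometric parameters (phase volumes,
    porosities, vessel surface ratios, cumulative mineral/vessel distance
    statistics), per-lacuna principal-axis shape descriptors, vessel-network
    skeleton orientation statistics and the level-of-alignment descriptor, and
    the Stokes-flow absolute-permeability tensor of the pore space with its
    eigenvalue anisotropy summary. Includes a synthetic bone-phantom generator
    with voxel-level ground truth for end-to-end validation, and paired
    two-sample statistics for recipient-versus-donor-site bone comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
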
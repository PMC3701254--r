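Package: sasmorph
Title: Synaptic Apposition Surface Extraction and Morphometry from
    Volumetric Segmentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts the synaptic apposition surface (SAS) from 3D binary
    segmentations of synaptic junctions reconstructed from FIB/SEM image
    stacks. The SAS is the internal free-form surface equidistant to the
    pre- and postsynaptic faces of the segmented junction; it is recovered
    by deforming a planar template mesh, seeded at the deepest point of a
    Gaussian-smoothed signed Euclidean distance map on anisotropic voxels,
    along the normal of the junction's oriented bounding box, then clipping
    it to the segmentation so that perforations survive as interior
    boundary loops. The surface is quantified (area, perimeter, area ratio,
    principal/mean/Gaussian curvature statistics) together with
    segmentation-level features (volume, Feret's diameter, equivalent
    ellipsoid, principal moments). Includes voxelized phantom generators
    with analytic ground truth for validation, NRRD/TIFF volume IO, PLY/OBJ
    mesh export, and a batch command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    tibble,
    tiff,
    generics,
    rlang,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
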
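Package: trabecula
Title: Trabecular Bone Morphometry and Phylogenetically Informed Allometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three-dimensional morphometry of trabecular bone from binary
    micro-CT volumes (bone volume fraction, connectivity density by the Euler
    characteristic, local thickness and separation by maximal inscribed
    spheres, bone surface density from a triangulated isosurface, and the
    mean-intercept-length fabric tensor with degree of anisotropy and main
    trabecular direction), cubic volume-of-interest selection inside a
    femoral head with resolution and connectivity quality filters, and
    phylogenetically informed comparative statistics (generalized least
    squares with Pagel's lambda, allometric scaling classification against
    dimensional isometry, pairwise lifestyle contrasts with
    Benjamini-Hochberg correction). Includes generators for geometric bone
    phantoms with analytic ground truth and for simulated comparative
    datasets on birth-process phylogenies, so the whole pipeline is testable
    without CT data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    igraph,
    nlme,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
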
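Package: fibremesh
Title: Morphometry of Electrospun Fiber Meshes from SEM Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Image-based morphometry for electrospun fiber meshes such as
    regenerated bacterial cellulose. Binarizes calibrated scanning electron
    micrographs, thins fibers to one-pixel-wide skeletons, and estimates
    fiber diameter distributions (distance-transform based), pore size
    distributions, total centerline length and total fiber surface area
    under a cylindrical-fiber model (lateral area per unit length pi*d).
    Also computes gravimetric water absorption capacity over soak time
    series and molar-mass-distribution averages (Mn, Mw, Mz, PDI). Includes
    a synthetic fiber-mesh generator with exact ground truth (centerlines,
    diameters, masks, analytic surface area) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
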
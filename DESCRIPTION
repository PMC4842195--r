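Package: hmrseg
Title: Hybrid Morphological Reconstruction and Marker-Controlled Watershed
    Segmentation for Medical-Style Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grayscale morphology primitives (geodesic reconstruction,
    opening- and closing-by-reconstruction, regional extrema), a hybrid
    morphological reconstruction (HMR) enhancement chain, Sobel gradient
    magnitude, and a marker-controlled watershed transform, composed into an
    end-to-end pipeline for segmenting layered and blob-like anomalies in
    8-bit medical-style raster images. Includes a synthetic phantom generator
    (concentric-ring artery cross-sections with controllable lumen occlusion,
    and retinal fundus-like discs with exudate and hemorrhage lesions) with
    exact ground-truth label maps, plus MIPAV-style region-of-interest
    quality metrics (area, perimeter, standard deviation, skewness, median)
    and severity-trend reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    tiff,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
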
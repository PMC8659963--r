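Package: canopycount
Title: Individual-Plant Detection and Counting from 3D Canopy Laser Scans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A five-step pipeline that turns raw multi-tray 3D laser scans of
    plant canopies (e.g. from phenotyping platforms scanning mung bean or
    chickpea trays) into per-tray individual-plant detections and counts.
    Steps: split a scan row into trays along the lineup axis and strip the
    tray frame; separate plants from soil by region growing segmentation on
    surface normals or by RANSAC ground-plane consensus; denoise with
    statistical outlier removal and rasterize the plant cloud to a 2D image
    whose colors encode height (blue low, green mid, red high); detect plants
    on the raster with a pluggable detector plus score/overlap post-filtering;
    and evaluate with IoU, precision/recall, COCO-style mAP and MAPE of the
    per-tray counts. Includes a synthetic scene generator with known ground
    truth, point-cloud and annotation I/O (ASCII PLY, XYZ, Pascal-VOC XML,
    CSV), ggplot2 visualisation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
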
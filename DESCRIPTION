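Package: podkit
Title: Bottom-Up Pod and Seed Phenotyping from Plant Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for keypoint-based phenotyping of legume pods in RGB
    plant images. Pods are modelled as unbranched chains of up to five
    seeds, analogous to persons and joints in bottom-up human pose
    estimation. The package provides the seed-to-pod point annotation
    grammar with Labelme-style JSON readers and writers, pod-centred
    training-crop sampling and fixed-stride tiling with coordinate
    remapping, a structural-prior (cosine-affinity) auxiliary loss that
    sharpens per-seed feature discrimination during training, a
    pod-adapted object-keypoint-similarity (OKS) metric with seed-count
    area correction and the matching and average-precision machinery
    built on it, dynamic-time-warping based merging of per-tile
    detections into whole-plant results, a synthetic scene generator
    that emulates pod geometry and detection noise, and a small pure-R
    convolutional training harness that exercises the full loss end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
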
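Package: cortlesion
Title: Detection and Quantification of Cortical Osteolytic Lesions in
    Micro-CT Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies cancer-induced osteolytic lesions in 3-D micro-CT
    volumes of cortical bone. The lesion-free bone surface is reconstructed
    by a two-stage volumetric diffusion (outward expansion to the maximum
    lesion diameter followed by a locally optimised inward contraction),
    lesions are obtained by subtracting the original volume from the
    reconstruction and labelled as 26-connected components, and per-lesion
    opening areas plus the total lesion area as a proportion of the bone
    surface are reported. Includes a 2-D silhouette baseline method, a
    synthetic cortical-shell phantom generator with analytic ground truth,
    slice-stack and NIfTI input, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    RNifti,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
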
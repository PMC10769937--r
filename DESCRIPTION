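Package: earalign
Title: Complete-to-Partial Non-Rigid Registration of Middle-Ear Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage non-rigid registration of a complete ex vivo middle-ear
    template point cloud onto noisy, partial in vivo point clouds such as those
    reconstructed from endoscopic optical coherence tomography. Stage one
    estimates an initial rigid alignment and a sparse correspondence set via
    pluggable backends (a geometric-descriptor matcher with RANSAC, or a
    provenance oracle for simulated data); stage two refines the alignment with
    a hierarchical deformation pyramid driven by sinusoidal positional
    encodings of increasing frequency, optimized per instance against a
    correspondence-masked Chamfer loss with displacement regularization. The
    package also ships a procedural simulator of segmented middle-ear anatomy
    (free-form lattice shape variants, articulated ossicular-chain poses,
    visibility- and occlusion-driven partial sampling, uniform jitter) with
    exact ground-truth displacement fields, the standard evaluation metrics
    (Chamfer distance, mean displacement error, per-structure landmark error,
    visible-points ratio), PLY/XYZ/CSV/JSON readers and writers, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
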
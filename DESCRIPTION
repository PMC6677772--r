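Package: neurotrace
Title: Quality Profiling and Collaborative Annotation Tools for
    Whole-Brain Neuron Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Headless toolkit for quality control of single-neuron
    reconstructions traced from teravoxel-scale light-microscopy brain
    images. Decomposes SWC reconstructions into neurite segments bounded
    by critical points (soma, branch points, terminal points), profiles
    per-segment image signal-to-noise ratio against the underlying
    volume using a critical-background statistic, classifies segments
    into four quality ranges, and summarises neuron-level quality as a
    length-weighted SNR with very-low-SNR and below-average-SNR length
    portions. Includes a chunked multi-resolution volume store with
    region-of-interest fetch, reconstruction comparison metrics (Sholl
    analysis, total-length consistency, pairwise spatial apartness),
    sharp-turn outlier alerts, a deterministic server-ordered command
    protocol for multi-annotator collaborative annotation with log
    replay, and seeded generators of synthetic neuron morphologies and
    rendered image volumes for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
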
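Package: latfuse
Title: Multi-Modal Medical Image Fusion via Latent Low-Rank Representation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fuses pairs of co-registered multi-modality medical images
    (CT/MR, T1/T2, MR with PET or SPECT). Each image is decomposed by a
    latent low-rank representation (LatLRR) solved with an inexact
    augmented Lagrangian multiplier scheme into a low-rank component
    carrying fine detail and a saliency component carrying energy.
    Low-rank components are fused through per-pixel class-score maps
    (fully convolutional network architecture or a deterministic filter
    bank backend), ZCA whitening, windowed l1-norm weight maps, weighted
    local energy and eight-neighborhood modified Laplacian selection, and
    a multi-rule Laplacian pyramid; saliency components are summed.
    Includes the five standard fusion quality metrics (entropy, Q_MI,
    Q^AB/F, SCD, VIFF), synthetic co-registered phantom generators, a
    YUV path for grayscale-with-RGB fusion, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    png,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
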
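Package: sensoangle
Title: Two-Dimensional Mapping of Sensory Integration on the Cortical Surface
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Characterizes sensory integration across the cortical surface
    with a two-dimensional model: a per-vertex sensory angle obtained by a
    hue transformation of non-negative regression coefficients on the mean
    signals of the primary visual, somatosensory, and auditory cortices,
    and a per-vertex sensory magnitude obtained by rank-rescaling the
    proportion of time-series variance those signals explain. Includes
    surface time-series input/output (delimited, GIFTI, CIFTI-2 dense
    formats), preprocessing (rest-volume trimming, standardization, run
    concatenation and session splitting), circular statistics for
    reliability and between-state comparison, sign-flip cluster-based
    permutation inference on triangulated meshes, meta-analytic hexagonal
    decoding of functional topic terms, and a synthetic surface-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    xml2,
    RNifti,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse
Config/testthat/edition: 3
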
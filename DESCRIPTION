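Package: fmricode
Title: Simulated fMRI Recovery of Similarity Structure Across Neural Coding Schemes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for asking which neural coding schemes are
    consistent with the success of functional MRI. Generates prototype and
    distortion stimulus sets, encodes them under candidate coding schemes
    (vector-space, gain-control, matrix-multiplication, perceptron, multi-layer
    random tanh networks, two-level full-factorial design coding, and SHA-1
    hash coding), measures recoverability of similarity structure with
    representational similarity analysis and a functional-smoothness statistic,
    and demonstrates the spatial and temporal sampling limits of voxel
    summation. Includes a seeded, fully reproducible experiment pipeline with
    structured text reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    openssl,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
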
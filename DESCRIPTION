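Package: sparsesynergy
Title: Sparse Muscle Synergies from Locomotor EMG Burst Phase Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies sparse muscle synergies from electromyographic (EMG)
    burst timing during locomotion. Burst onset and offset times are expressed
    as phases of a normalized step cycle and clustered in the phase plane by an
    associative rule: bursts whose +/-1 SD rectangles overlap along the
    inter-centroid axis are merged into equivalence classes (synergies).
    Includes a constrained mode that fixes synergy composition to a reference
    condition, piecewise-Gaussian direct-component activation profiles,
    correlated bivariate-normal confidence ellipses, condition statistics for
    phase and duration-normalized burst magnitude, and a synthetic burst-data
    generator with planted synergy structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
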
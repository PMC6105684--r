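Package: finpigment
Title: Pigmentation-Based Photo-Identification of Dolphin Dorsal Fins
Version: 0.1.0
Authors@R:
    person("Catalogue", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying individual delphinids from dorsal-fin
    pigmentation when nicks and notches are rare. Provides catalogue input
    and output with photographic-quality grading, intensity normalisation
    within the fin mask, iterative-closest-point registration of fin
    contours under a projective transform, two pose-robust subdivisions of
    the fin (a 33-patch grid anchored to the fin base and a 9-patch
    distance-transform/medial-axis partition), a 142-dimensional
    pigmentation feature vector, individual identification with a
    shrinkage-regularised linear discriminant classifier evaluated by
    leave-one-out cross-validation, a permutation seriation test with
    Sidak-corrected decisions for pigmentation stability over time, and a
    ground-truthed synthetic fin-catalogue generator for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    FNN,
    jsonlite,
    png,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    MASS,
    vegan,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
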
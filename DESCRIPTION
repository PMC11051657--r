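Package: lamellakit
Title: Lamella Geometry and Particle-Quality Analysis for Cryo-ET
    Subtomogram Averaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to curate subtomogram-averaging particle sets from
    cryo-focused-ion-beam-milled lamellae. Straightens template-matching
    coordinates by fitting a reference plane per tomogram, locates the two
    lamella surfaces from the flattened-Z histogram, and derives per-particle
    depth and local lamella thickness. Stratifies particles into equal-count
    thickness groups, fixed-size depth bins, high-quality selections, and
    nested random subsets with distribution checks. Computes Fourier shell
    correlation between half-maps with threshold-crossing resolution,
    Rosenthal-Henderson B-factor fits of resolution against particle number,
    and an explicit hinge-regression estimate of the ion-damage-layer depth
    from normalized cross-correlation profiles. Includes dose-symmetric
    tilt-scheme generation with critical-exposure dose weights, minimal
    STAR and MRC readers and writers, and a synthetic wedge-lamella data
    generator so every stage is testable without tomograms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
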
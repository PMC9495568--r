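Package: probead
Title: Release Kinetics, Morphometry and Design Optimization for
    Probiotic Encapsulation Beads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing controlled release of encapsulated
    probiotic cells from hydrogel beads during simulated gastrointestinal
    digestion. Fits the classical release models (zero-order, Higuchi,
    Korsmeyer-Peppas, Peppas-Sahlin), classifies transport mechanisms from
    the release exponent and from diffusion/relaxation term contributions,
    computes Damkohler numbers coupling in-bead growth to cell release, and
    detects the equilibrium point between released and retained viable
    cells. Includes bead-micrograph morphometry (thresholding, shape
    descriptors, skeletonization, grey-level co-occurrence texture
    features, box-counting fractal dimension, gliding-box lacunarity and
    shifting differential box counting), 3x3 factorial response-surface
    fitting with desirability optimization of wall-material composition,
    encapsulation-efficiency and plate-count arithmetic, and a synthetic
    data generator that emulates the measurement structure of in vitro
    digestion studies for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    minpack.lm,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
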
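Package: redoxdyn
Title: Dual-Emission Autofluorescence Imaging Analysis of Cellular Redox Dynamics
Version: 0.1.0
Authors@R:
    person("Jordan", "Reyes", email = "jreyes.imaging@posteo.net", role = c("aut", "cre"))
Description: Analysis pipeline for split field-of-view, dual-emission
    autofluorescence microscopy of cellular metabolism. Frames carrying
    side-by-side 451-nm (NAD(P)H) and 560-nm (FAD) half-images are split,
    registered and reduced to per-cell intensity traces; the package computes
    the optical redox ratio 451/(451+560), first/last-window photobleaching
    percent change, contrast signal-to-noise ratios, and stimulus-response
    kinetics (baseline drift, onset delay, rise rate, time-to-peak), and
    compares groups with a Shapiro-Wilk-gated t-test / Mann-Whitney U test.
    A synthetic imaging simulator generates split-frame TIFF time-lapse
    stacks with known ground truth (cell phantoms, monoexponential
    photobleaching, Poisson shot noise, cyanide- and glucose-type
    perturbations) so every stage is testable without raw microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
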
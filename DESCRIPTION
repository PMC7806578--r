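Package: tandemgc
Title: Untargeted Fingerprinting of Tandem-Ionization GCxGC-TOF MS Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulation, processing, alignment, and class comparison of
    comprehensive two-dimensional gas chromatography time-of-flight mass
    spectrometry (GCxGC-TOF MS) runs acquired with tandem (dual energy,
    12 eV + 70 eV) electron ionization. Provides a synthetic dual-energy
    chromatogram generator with known ground truth, channel fusion by
    stream summing, rolling-ball background subtraction, watershed 2D peak
    detection, NIST-style direct and reverse spectral match factors,
    template-based cross-sample alignment with reliable peaks and
    untargeted peak regions, nonparametric feature selection
    (Kruskal-Wallis with Dunn's post hoc and Bonferroni correction),
    PLS-DA variable importance in projection, linear retention index
    identification, and fuzzy-ratio comparison of composite class images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
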
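Package: glottovib
Title: Glottovibrogram Analysis of High-Speed Laryngeal Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying vocal fold, ventricular fold and vocal
    membrane vibration in excised-larynx experiments from high-speed video,
    calibrated sound pressure and bronchial pressure recordings. Builds
    glottovibrograms (glottal opening width versus time and
    anterior-posterior position) by gray-threshold segmentation or by
    scan-line edge tracking for translucent membranes, estimates fundamental
    frequency with the yin algorithm or spectrogram ridge tracking, verifies
    the vibration-sound frequency lock by identity regression, and measures
    phonation threshold pressure and its rate of change at sound onset. A
    synthetic trial generator with exact kinematic ground truth supports
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    EBImage,
    tiff,
    jsonlite,
    data.table,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
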
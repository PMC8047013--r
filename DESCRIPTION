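Package: csdquant
Title: Quantification of Cortical Spreading Depolarization Imaging and
    Electrophysiology Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for KCl-induced cortical spreading
    depolarization (CSD) experiments in mice: widefield transcranial
    calcium-wave detection with half-maximum arrival/passage timing and
    propagation-speed estimation, band-limited RMS amplitude and
    post-CSD recovery curves, two-photon astrocyte high-calcium event
    probability and pairwise soma correlation statistics, ion-selective
    potassium microelectrode calibration and concentration
    reconstruction, and whisker-evoked LFP amplitude quantification.
    Includes a seeded synthetic-data generator that emulates the imaging
    and electrophysiology signal structure so every estimator is
    verifiable by parameter recovery without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    tiff,
    yaml,
    EBImage,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
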
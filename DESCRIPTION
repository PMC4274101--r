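Package: cuffmap
Title: Quantification of Arterial-Wall Macromolecule Uptake Around a
    Tapered Perivascular Cuff
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for en-face confocal quantification of
    tracer uptake by the arterial wall around a tapered perivascular
    cuff, with companion lumen morphometry and hemodynamic
    post-processing.  Provides flat-field and depth-attenuation
    correction, luminal-surface detection by thresholding, depth-windowed
    maximum projection, circumferential averaging and group statistics
    for two-channel image stacks; cross-sectional area, perimeter, shape
    index (4*pi*A/P^2) and maximum-inscribed-circle morphometrics along a
    vessel centerline with cuff fitting; wall shear stress and pressure
    band statistics, Murray-law flow splits, Reynolds numbers, velocity
    scalings and a quasi-1D viscous stenosis surrogate; Doppler envelope
    beat segmentation and peak / end-diastolic / cycle-averaged velocity
    metrics; and deterministic synthetic-data generators with stored
    ground truth so every stage is testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    yaml,
    jsonlite,
    signal,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
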
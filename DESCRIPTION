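Package: nanochrome
Title: Chromatic Digital Counting of Single Plasmonic Nanoparticles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end modelling and analysis toolkit for dual-band dark-field
    imaging of single gold nanoparticles. Computes coated-sphere Mie scattering
    spectra of protein-coated gold cores, models a multi-filter two-band
    (green/red) detection path and the per-particle spectral chromatic contrast
    gamma = (R - G)/(R + G), simulates ground-truthed two-channel image stacks
    of flowing nanoparticles with shot noise and aggregates, detects and
    photometers diffraction-limited spots, and turns per-spot gamma tables into
    a digital sensing readout: Gaussian fit of the negative-control gamma
    distribution, upper-95%-CI counting cutoff, delta-NP% count-rate
    statistics, log-concentration standard curves, limits of detection and
    quantification, and recovery rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
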
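Package: ndrms
Title: Electrode-Density Analysis of Epicortical Recordings with the
    Normalized Differential Root Mean Square
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the non-shared information between pairs of
    electrocorticography (ECoG) electrodes as a function of inter-electrode
    distance, electrode size and frequency band, using the normalized
    differential root mean square (ndRMS): the RMS of the difference between
    two z-normalized band-passed signals, bounded by 0 (identical signals),
    sqrt(2) (independent white noise) and 2 (antiphase oscillations).
    Includes electrode-grid geometry and equidistant pair binning, a
    volume-conduction forward simulator of epicortical potentials with
    traveling oscillations and power-law broadband activity, signal
    preprocessing (bad-channel detection, harmonic notch filtering, common
    median referencing, Butterworth band-pass and Morlet band power), trial
    segmentation, distance-resolved ndRMS and correlation curves,
    rank-sum comparison of grids at matched distances, and high-gamma task
    response mapping with signed R-squared statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
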
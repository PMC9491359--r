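Package: fpvs
Title: Frequency-Tagged Oddball Analysis for Fast Periodic Visual Stimulation MEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fast periodic visual stimulation (FPVS) oddball
    experiments in MEG/EEG: combinatorial construction of morphologically
    structured pseudoword stimuli and constraint-satisfying periodic
    stimulation sequences; simulation of multi-channel sensor recordings
    with known steady-state responses, 1/f background and sensor noise;
    frequency-domain quantification of oddball responses via
    signal-to-noise-ratio (SNR) spectra normalized by surrounding bins;
    and a sensor-space one-sample cluster-based permutation test against
    the SNR noise level of 1, with triangulation-based sensor adjacency
    and sign-flip Monte Carlo randomization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
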
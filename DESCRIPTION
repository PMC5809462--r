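Package: toiHRV
Title: Contactless Heart Rate and Heart Rate Variability from Facial Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Transdermal optical imaging pipeline for contactless measurement
    of heart rate and heart rate variability from RGB facial video. Frames are
    decomposed into bitplanes, a signed combination of bitplanes is selected by
    greedy maximisation of cardiac-band spectral signal-to-noise ratio to
    compose a hemoglobin-concentration signal per facial region of interest,
    and heartbeat peaks are reconstructed from the cardiac intrinsic mode
    function of a Hilbert-Huang decomposition. Includes an ECG reference branch
    (energy-based R-wave detector), Poincare SD1/SD2 analysis of R-R interval
    series, Bland-Altman and correlation method-agreement statistics, and
    ground-truthed synthetic generators (RSA-modulated R-R intervals, ECG
    waveforms, facial video with a pulse embedded in chosen bitplanes) so the
    whole pipeline can be exercised end to end without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
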
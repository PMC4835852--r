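Package: flyrhythm
Title: Waveform Modeling and Harmonic Spectral Analysis of Drosophila
    Locomotor Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Models multiday Drosophila locomotor activity as a periodic
    four-exponential waveform with a single primary period, computes its
    closed-form harmonic power spectrum, and fits the model to
    beam-crossing recordings through a two-stage (time-domain then
    spectral-domain) procedure. Includes Lomb-Scargle and maximum-entropy
    (Burg/Andersen) spectral estimation with false-alarm significance
    levels, autocorrelation with significance bounds, Dirichlet-kernel
    side-peak prediction, harmonic matching and fit-accuracy metrics,
    TriKinetics activity-monitor file input/output, an inhomogeneous
    Poisson simulator of activity records for wild-type and clock-mutant
    genotypes, and a demonstration that low-pass filtering aperiodic
    noise manufactures spurious spectral peaks.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
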
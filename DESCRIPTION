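Package: puffsnr
Title: Fluorescence Fluctuation Modeling and Signal-to-Noise Prediction for
    Calcium Puff Linescan Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the sources of fluorescence fluctuation in
    single-wavelength calcium-dye confocal linescan imaging.  An extended
    Number & Brightness model describes per-pixel photon-counting
    fluorescence as a Poisson molecule-number, binomial calcium-binding,
    Poisson photon-emission, Poisson detector chain.  The model parameters
    (detector gain, bound/free molecular brightness, binding occupancy and
    mean molecule number) are calibrated from variance-versus-mean moment
    curves measured in three kinds of stationary experiments.  A spherically
    symmetric reaction-diffusion simulator of calcium, indicator dye, EGTA
    and endogenous buffers around a stochastic channel-cluster source,
    combined with a confocal point-spread-function blur, produces realistic
    occupancy maps from which noisy synthetic linescan images, expected
    signal-to-noise ratios and equivalence classes of experimental settings
    are computed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    tiff,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
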
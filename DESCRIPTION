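Package: thzfb
Title: Terahertz Time-Domain Spectroscopy and Imaging for Foreign-Body
    Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for detecting low-density organic foreign
    bodies (insect fragments) in plant-material matrices such as finishing
    tea by terahertz time-domain spectroscopy (THz-TDS) and time-of-flight
    reflection imaging.  Provides FFT conversion of time-domain pulse
    traces to amplitude spectra, three penalized least-squares baseline
    correction algorithms (asymmetric least squares, adaptive iteratively
    reweighted penalized least squares, and sparsity-assisted baseline
    estimation and denoising), k-nearest-neighbour and partial least
    squares discriminant analysis classifiers with calibration/prediction
    accuracy accounting, grayscale-windowed time-of-flight image analysis
    with shape-based blob detection, and a seeded phenomenological pulse
    generator that supplies ground-truth baselines, labels and masks for
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    EBImage,
    png,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
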
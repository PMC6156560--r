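Package: irdenoise
Title: Benchmarking Spectral and Spatial Denoising for FT-IR Hyperspectral Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates ground-truth infrared hyperspectral images of tissue
    cores (mixed Gaussian-Lorentzian band spectra, fuzzy component maps,
    wavelength-dependent spatial blur, randomized baselines and
    scan-number-dependent noise), applies the standard spectral denoisers
    (Savitzky-Golay, Fourier low-pass, wavelet shrinkage, PCA reconstruction,
    minimum noise fraction) and per-band spatial filters (mean, weighted mean,
    Gaussian, median, 2-D Fourier, 2-D wavelets), and scores them with
    signal-to-noise-ratio gain, signal distortion, linear peak-SNR gain and
    the structural similarity index.  Includes ENVI cube I/O, pixel binning
    between high-definition (1.1 micron) and standard (5.5 micron) grids, and
    a benchmark orchestrator with parameter sweeps and optimum selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
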
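Package: mdoct
Title: Multi-Directional Spectral-Domain OCT Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-directional (three-beam) spectral-domain optical
    coherence tomography of the retina: a forward simulator that renders
    three-channel retinal phantoms with known layer boundaries, directional
    layer reflectance and speckle; standard SD-OCT reconstruction (mean
    spectrum subtraction, lambda-to-k resampling, numerical dispersion
    compensation, FFT); rigid inter-channel registration, flattening and
    volume fusion; graph-based ILM/RPE layer segmentation; layer-anchored
    directional-reflectivity quantification with azimuthal profiles, sector
    detection, additive colour fusion and maximum-intensity-projection
    compensation; and speckle-reduction metrics (SNR, CNR, ENL).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
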
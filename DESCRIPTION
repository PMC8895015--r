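Package: specklekit
Title: Coherent Diffraction Imaging Simulation, OSS Phase Retrieval and
    Radiation-Damage Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for lensless coherent diffraction imaging (CDI) of weakly
    scattering biological specimens. Simulates oversampled far-field speckle
    patterns from synthetic electron-density phantoms, with Poisson photon
    noise, beamstop masking with Friedel-symmetry infill, and detector binning
    with deconvolution of the binning contrast loss. Phases patterns with the
    oversampling-smoothness (OSS) iterative algorithm using ensemble restarts,
    then selects mutually consistent reconstructions by convolutional feature
    embedding, principal components and k-means++ clustering before averaging.
    Quantifies reconstruction quality with the phase-retrieval transfer
    function (PRTF), Wiener-weighted PRTF resolution at the 1/e criterion,
    shell amplitude variance and shell cross-correlation, and quantifies
    radiation-induced structural change across a dose series through electron
    totals, region density trajectories and lateral density profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
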
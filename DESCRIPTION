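Package: ldics
Title: Lipid Droplet Quantification in Label-Free Nonlinear Microscopy by
    Image Correlation Spectroscopy and Particle Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies the number density and size of lipid droplets in
    label-free third-harmonic-generation (THG) microscopy images of fungal
    hyphae.  Implements the full analysis chain: hypha segmentation and
    iterated background subtraction that suppresses the bright cell-wall rim,
    image correlation spectroscopy (ICS) with Lorentzian fitting of the
    central autocorrelation profile and amplitude-based droplet counting,
    threshold-based particle size analysis (PSA) as an independent
    cross-check, two-channel colocalization (Pearson correlation and the
    ICCS interacting-cluster fraction), and batch reporting with
    area-normalized diameter histograms.  A synthetic hypha-image generator
    with full ground truth (droplet positions, diameters, wall and mask
    geometry) supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
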
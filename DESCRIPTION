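Package: smquant
Title: Single-Molecule Tracking, Diffusion-State and Cluster Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification stack for single-molecule microscopy of membrane
    proteins and amyloid assemblies: mean-squared-displacement diffusion
    analysis of single-particle trajectories (diffusion coefficient and
    explored-area statistics), variational-Bayes hidden-Markov inference of
    diffusive states from thousands of short trajectories, DBSCAN cluster
    analysis of super-resolution (STORM) localization data, a-trous
    wavelet-based segmentation and co-localization of fluorescence cluster
    images, and conversion between monomer-equivalent and particle
    concentrations of fibril preparations from electron-microscopy geometry.
    A synthetic-data module generates trajectories, localization clouds and
    images with known ground truth so every stage can be validated.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
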
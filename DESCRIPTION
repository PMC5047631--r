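Package: npreflect
Title: Quantitative Analysis of Nanoparticle Uptake in Reflectance Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for label-free imaging of nanoparticle uptake in cells by
    reflectance confocal microscopy (RCM) and reflectance structured
    illumination microscopy (R-SIM). Provides a synthetic multi-modality scene
    generator with anisotropic Gaussian point spread functions and
    Poisson-Gaussian noise, control-baseline k-means segmentation of
    nanoparticle reflectance signal, connected-component quantification and
    object-based cross-modality co-occurrence, line-profile full width at half
    maximum (FWHM) resolution estimation, and multimodal registration
    (point-pair least squares, intensity-based with preprocessing, and
    Coherent Point Drift), plus a seeded end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    graphics,
    grDevices,
    tiff,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
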
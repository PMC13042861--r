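Package: sculptrace
Title: Quantitative Surface Traceology for Stone-Carving Techniques
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discriminating stone-carving techniques (pecking,
    scraping, polishing, engraving and their superimpositions) and sculptor
    expertise from 3D surface micro-topography. Implements areal surface
    texture parameters (ISO 25178), scale-sensitive fractal analysis (Asfc,
    epLsar, HAsfc), furrow-network and texture-direction analysis, elliptic
    Fourier morphometrics of engraving cross-sections, and the statistical
    layer used in quantitative traceology: circular statistics with
    permutation p-values, correlation-based variable selection, PCA,
    cross-validated linear discriminant analysis with kappa/NIR reporting,
    and permutation MANOVA. A synthetic-surface generator emulating
    limestone squares worked by the different techniques makes the whole
    pipeline testable without access to physical scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    MASS,
    caret,
    EBImage,
    yaml,
    zoo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
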
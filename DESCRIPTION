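Package: tiledtm
Title: Tiled Cryo-EM Acquisition, 2D Template Matching and Montage Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for whole-lamella cryo-EM imaging with a condensed beam:
    planning serpentine hexagonal grids of beam-image-shift positions over a
    FIB-milled lamella, simulating tile exposures with planted macromolecular
    targets, pre-processing tiles (illumination masking, Gaussian noise fill
    of unilluminated pixels, central-crop movie alignment, exposure filtering,
    CTF estimation, Beer-Lambert ice-thickness estimation), detecting targets
    by exhaustive 2D template matching with an extreme-value
    one-false-positive detection threshold, assembling tiles into a montage
    by masked cross-correlation and global least-squares refinement, and
    summarising per-lamella detection statistics.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
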
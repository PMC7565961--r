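Package: myomorph
Title: Cardiomyocyte Morphometry and Connexin-43 Lateralization from
    Fluorescence Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Automatic detection and morphometric characterization of
    cardiomyocytes in multi-channel immunofluorescence images of cardiac
    tissue, together with quantification of connexin-43 (CX43) expression
    and of its polar-versus-lateral distribution. Cell masks are built by
    per-channel thresholding and binary morphology, individual cells are
    delineated by border following and enclosed in minimum-area rotated
    rectangles, and each rectangle is split into polar and lateral
    compartments to estimate the CX43 lateralization percentage. The
    package also quantifies agreement between manual and automatic cell
    masks through overlap percentile curves, and ships a synthetic
    fluorescence scene generator with exact vector ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    optparse,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
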
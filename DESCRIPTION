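Package: poleprofile
Title: Posterior Pole Profile and Optic Disc Configuration from En Face OCT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to locate the deepest point of the eyeball (DPE) from
    consecutive en-face (coronal) swept-source OCT sections and to relate its
    position to optic disc tilt, torsion and ovality. Includes a ground-truthed
    synthetic eye-phantom generator that renders posterior-pole surfaces into
    multi-page TIFF volumes with JSON sidecars, an automated detector for the
    hyper-reflective Bruch's membrane/choroid interface, posterior-pole metrics
    with the field's sign conventions, a four-region DPE classifier, an
    oblique-projection geometric model predicting torsion and ovality, and a
    statistics layer (two-way mixed-model intraclass correlation, group
    comparisons, Pearson correlations and screened multivariate regression).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
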
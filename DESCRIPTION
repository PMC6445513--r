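Package: ricmatch
Title: Radial Template Matching for Soft Colloidal Probe RICM Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Automated detection and measurement of the circular interference
    fringe patterns that soft colloidal probes (elastic hydrogel microspheres)
    produce in reflection interference contrast microscopy (RICM). Radial
    intensity templates are generated from the interference forward model of a
    sphere above a planar coverslip, including a finite illumination-aperture
    envelope and an empirical exponential decay. A gradient-voting line image
    prunes the search space, candidate centers are scored by Pearson
    correlation of the azimuthally averaged radial profile against a template
    bank, and detections are refined by a slope-synchronism fit of the fringe
    extrema. Detected templates yield particle radius, contact radius, and --
    via Johnson-Kendall-Roberts contact mechanics -- the adhesion energy.
    Includes a ground-truthed synthetic scene generator and an intensity-based
    (region-growing) contact-radius reference measurement for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    png,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
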
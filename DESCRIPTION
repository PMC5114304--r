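Package: myelinmapr
Title: Reliability Metrics and Areal-Border Analysis for Surface-Based
    Cortical Myelin Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to compare quantitative and weighted magnetic resonance
    relaxometry parameters (R1, T1w, T2*, T2*w and their ratios) for
    myelin-based cortical surface mapping. Implements mono-exponential T2*
    fitting from multi-echo gradient-echo signals, per-vertex
    FWHM-normalized inter- and intra-subject coefficients of variation,
    parcellability variation, contrast-to-noise ratio per unit scan time,
    depth-resolved vertex-wise correlations, and two areal-border methods
    (AUC-threshold contours and tangent-plane surface gradients), together
    with a seeded synthetic cortical phantom that emulates a
    multi-subject scan-rescan study design on a triangulated surface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    xml2,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
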
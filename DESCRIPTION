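Package: cytofocus
Title: Semantic Autofocus Simulation and Sharpness Scoring for
    Liquid-Based Cytology Slide Scanning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying single-layer whole-slide scanning of
    liquid-based cytology (LBC) preparations. Provides a virtual LBC
    slide simulator with a three-dimensional cell layer, a dust layer
    and defocus optics; rule-based validity filters (object size, Canny
    edges, HSV stain color) that decide whether an autofocus probe
    landed on cellular material; a five-feature support-vector-machine
    sharpness classifier that scores whole-slide focus quality per
    region; the closed-loop iterative scan-control workflow that places
    focus points, builds a focus map and re-scans until the slide is
    sharp; z-profile statistics for focus-point height datasets; and
    binary classification metrics shared by the evaluation paths.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    jsonlite,
    yaml,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
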
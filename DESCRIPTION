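Package: grassunmix
Title: Fractional Cover Change Analysis for Grasslands via Constrained
    Linear Spectral Unmixing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping fractional land-cover change in semi-arid
    grasslands from hyperspectral imagery. Implements fully constrained
    linear spectral unmixing (non-negativity and sum-to-one) of
    reflectance cubes against ROI-derived endmember libraries, per-pixel
    two-date trend slopes, histogram and weighted-area summaries of
    fractional abundance, threshold-based confusion-matrix accuracy
    assessment, and exact Wilcoxon signed-rank and Shapiro-Wilk change
    tests. A seeded synthetic scene generator emulating airborne
    hyperspectral acquisitions (1 m pixels, 426 bands at 5 nm) provides
    ground truth for end-to-end validation without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr,
    mgcv,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
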
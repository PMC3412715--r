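Package: iip3d
Title: Arbitrary-Plane Virtual Sectioning and Tiled Delivery of 3D Biological Images
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Interval-coded volumetric image objects with arbitrary-plane virtual
    sectioning, in the style of atlas virtual-microtome services. Provides
    run-length (interval) coded 3D spatial domains with value tables, compound
    objects of possibly overlapping labelled regions, a pitch/yaw/roll sectioning
    transform with statue, up-is-up, fixed-line and absolute viewing modes, tiled
    multi-resolution section delivery with PNG/JPEG encoding, indexed overlay
    compositing with per-region colour and alpha, an IIP-style request protocol
    with object queries, three-level caching and substring proxy routing, and a
    chunked block store so larger-than-memory volumes can be sectioned touching
    only the intersecting blocks. Synthetic phantom generators give every
    component a test substrate with closed-form answers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    jpeg,
    tiff,
    RNifti,
    jsonlite,
    digest,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
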
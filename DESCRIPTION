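Package: cellfile
Title: Cell Counting and Measurement Along Profile Lines in Confocal Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Counts and measures individual neighbouring cells along a
    user-defined profile line in single-channel confocal-style images of
    wall-stained tissue (e.g. propidium-iodide stained Arabidopsis roots).
    A spline is fitted through the user's polyline, image intensity is
    sampled at uniform arc-length steps, cell walls are detected as
    windowed intensity peaks subject to a stringency rule, and per-cell
    lengths are derived from consecutive wall positions. The onset of
    rapid cell elongation (the transition-zone landmark) is estimated as
    the break point of the cell-number versus cell-length curve via the
    maximum-perpendicular-distance-to-chord rule, and landmark estimates
    can be validated against rater panels with the Williams Index. A
    synthetic image generator provides ground-truthed cell-file images
    for testing, and a command-line script supports batch use.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    tiff,
    grDevices,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
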
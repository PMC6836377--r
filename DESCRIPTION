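Package: planaquant
Title: Quantification of Planarian Behavioral Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify arena-based behavioral assays of freshwater
    planarians. Computes the feeding index (ratio of binarized ingested-food
    fluorescence area to projected whole-body area) from two-channel images,
    trajectory endpoints for food-localization and photo-orientation assays
    (median speed, percent reaching the food, target-quadrant occupancy, a
    speed-compensated food-localization index, occupancy heat maps), ciliary
    beat frequency from kymograph line scans of high-frame-rate video, and
    population-growth summaries with doubling times. A seeded synthetic-data
    generator (biased correlated random walks, rendered feeding images,
    oscillating-cilia video, branching-process growth) provides ground truth
    for every stage, and a normality-gated group-comparison workflow with
    Holm correction reproduces the standard nonparametric statistics used for
    such assays.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    yaml,
    tiff,
    png,
    nortest,
    multcomp,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
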
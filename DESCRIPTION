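Package: mscope
Title: Montage Selection Analysis for Transcranial Direct Current Stimulation Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing and montage-selection analysis for simulated
    transcranial direct current stimulation (tDCS) current-density fields.
    Given per-node cortical coordinates, per-montage magnitude-of-current-density
    values and an anatomical parcellation (hemisphere, lobe, gyrus), the package
    implements a three-principle selection procedure: lobe selectivity
    configuration analysis (per-lobe means, max_MCD, avg_MCD exceedance and
    spread), thresholded-overlap statistics between montage pairs (the p and r
    ratios at 50%-of-maximum thresholding), and gyrus-cluster ranking by total
    current density (CMCD). A seeded synthetic head model, 10-10 electrode
    layout and phenomenological field generator emulate finite-element
    simulator output so the full pipeline, including electrode-displacement and
    intensity sensitivity analyses, runs end to end without external solvers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
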
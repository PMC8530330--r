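Package: pupilkinetics
Title: Pupil Reaction Detection in Cataract Surgery Videos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects pupil reactions (sudden constrictions or dilations of the
    pupil) in cataract surgery videos from per-frame pupil and iris
    segmentations. Tracks pupil and limbus widths across frames, fills
    measurement gaps, smooths the width signals with a zero-phase Butterworth
    low-pass filter, segments the smoothed signal at its extrema and retains
    size changes exceeding a fraction of the median limbus-pupil width
    difference. Includes interval-matching evaluation metrics (Recall,
    Precision, Ground Truth Coverage Rate and their harmonic mean), a grid
    search over the detector hyperparameters, and a synthetic width-signal
    generator for end-to-end testing without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
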
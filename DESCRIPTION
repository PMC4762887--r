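Package: flypref
Title: Multi-Fly Arena Tracking and a State-Transition Model of Sugar Preference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying two-choice sugar preference of walking
    Drosophila in a circular arena. Provides a ground-truthed synthetic arena
    generator (correlated random walkers with side-dependent speeds and
    feeding-state dynamics, rendered as noisy grayscale frames), a multi-fly
    video tracker (background-subtracted segmentation, likelihood-based
    detection of merged blobs with iterative re-thresholding, second-moment
    ellipse fitting, greedy closest-neighbour frame-to-frame association and
    kinematics), behavioural read-outs (preference index, pooled velocity
    summaries, proboscis extension fractions, sigmoid dose-response fits) and
    a four-state dynamic transition model that predicts sugar preference from
    taste affinity and locomotion suppression, with calibration and
    theoretical mutant simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    deSolve,
    minpack.lm,
    png,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
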
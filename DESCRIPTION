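Package: metadetect
Title: Simulation and Analysis of Metacognition for Visual Detection and
    Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative models of decision confidence for visual detection
    (yes/no) and discrimination (clockwise/anticlockwise) tasks: a static
    unequal-variance signal detection observer, a dynamic criterion-updating
    observer, and an attention-monitoring observer, together with a behavioural
    task simulator (adaptive signal-to-noise staircases, six-point confidence
    scale, bonus schedule, exclusion rules), metacognition metrics
    (response-conditional type-2 ROC curves and their area, meta-d' and
    metacognitive efficiency), and a two-step quadratic confidence-profile
    analysis with ordinary-least-squares group inference and
    Jeffreys-Zellner-Siow Bayes factors. All analyses run on synthetic data
    produced by the included simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
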
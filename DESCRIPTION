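Package: crosslearn
Title: Linear and Nonlinear Visual Feature Learning with Cross-Shaped Stimuli
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying linear versus nonlinear (XOR-like, symmetry)
    visual category learning with parametric cross-shaped stimuli. Provides
    stimulus construction and rendering, pixel-level and V1-model
    (Gabor filter bank) dissimilarity metrics, a perceptron readout that
    certifies linear separability, a synthetic two-alternative behavioral
    simulator emulating rodent touchscreen sessions (with correction trials)
    and human trial streams (with blocked pseudo-randomization), backward
    learning-curve construction with constrained logistic-growth fitting,
    and template-based strategy analysis with exact binomial intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
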
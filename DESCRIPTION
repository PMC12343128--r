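Package: piece
Title: Causal Inference and State Estimation Models of Trial-by-Trial
    Sensorimotor Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the sensorimotor system parses total
    movement error into internally generated error (motor noise and bias,
    IGE) and externally generated error (imposed visuomotor rotation, EGE).
    Implements a Bayesian observer that combines visual, proprioceptive and
    motor-prediction cues, performs causal inference over whether feedback
    was perturbed, and derives single-trial adaptation from precision-
    weighted state estimation of the perturbation. Three rival single-trial
    models that align the perceived hand with the target (proprioceptive
    re-alignment, perceptual-error adaptation, and relevance estimation)
    are provided behind the same predict/simulate interface. Includes a
    generator for randomized rotation-triplet reaching protocols, the
    triplet-based IGE/EGE regression analyses, per-participant maximum-
    likelihood fitting with BIC model comparison, posterior predictive
    checks, and parameter- and model-recovery harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    lhs
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    jsonlite
Config/testthat/edition: 3
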
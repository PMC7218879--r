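Package: actionkeys
Title: Keyframe-Based 3D Skeleton Action Recognition
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for recognising human actions from motion-capture joint
    trajectories. Poses are normalised to remove global translation and
    heading, motions are summarised to informative keyframes by an iterative
    nearest-neighbour/median selection algorithm, and actions are classified
    with a two-hidden-layer sigmoid/softmax network trained by explicitly
    derived backpropagation, with a per-frame majority vote deciding the
    action. Includes a labelled-dataset CSV layout, a synthetic multi-class
    motion generator for end-to-end testing, a stratified k-fold
    cross-validation harness, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr
Config/testthat/edition: 3
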
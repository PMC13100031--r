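Package: reflexgait
Title: Reflex-Modulated Speed Control in Simulated Bipedal Locomotion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Planar neuromusculoskeletal simulation of human walking and
    running driven entirely by spinal-reflex feedback: a seven-segment
    rigid-body model actuated by 18 Hill-type musculotendon units, a
    71-parameter delayed length/force reflex network, CMA-ES optimization
    of locomotion speed, principal-component selection of the key reflex
    parameters, a polynomial speed-modulation function for offline and
    online (run-time) target-speed tracking, and abrupt-switch walk-run
    gait-transition experiments. Includes a reduced muscle-driven hopper
    testbed so the full pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
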
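Package: hedgereach
Title: Reach Planning Under Goal Uncertainty: Sigmoid Latency Analysis and
    Optimal Control with an Evolving Belief State
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing target-jump ("double-step") reaching
    experiments and for the normative theory of intermediate movements.
    Includes a generator of synthetic timed-response sessions with known
    ground truth; kinematic preprocessing (Savitzky-Golay smoothing,
    tangential-velocity onset detection, initial reach direction, curvature
    exclusion); maximum-likelihood errors-in-variables fitting of the
    sigmoidal relationship between re-preparation time and initial reach
    direction, with a shallow-slope penalty and an expectation-maximization
    outlier mixture; and a one-dimensional optimal feedback control model in
    which the goal is uncertain and belief about it evolves as a log-odds
    random walk, solved by backward dynamic programming to yield predicted
    initial-reach-angle policy curves, including asymmetric-cost and barrier
    variants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
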
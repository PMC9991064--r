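Package: circuitcat
Title: Learning Dynamics and Activity Evolution in Categorization Circuits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates a two-layer feedforward circuit that learns simple and
    context-dependent categorization tasks by full-batch gradient descent on a
    quadratic loss, and implements the matching large-width analytical theory:
    Gaussian population averages computed by Gauss-Hermite quadrature, reduced
    linear systems for the activity coordinates, linearized (lazy-regime)
    predictions of post-learning activity, and closed-form predictions for
    category/context selectivity, clustering, signal correlations and response
    asymmetry. Includes task generators, activity measures, parameter-sweep
    harnesses and comparison reports between theory and simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    tools,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
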
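Package: windtree
Title: Functional-Structural Forest Simulation Under Wind Loads and Light
    Competition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An individual-based functional-structural model of trees that
    grow segment by segment while competing for light and withstanding
    wind-induced bending loads. Trees carry a 34-gene genome decoded into
    branching angles and two small neural networks that set carbon
    allocation (primary growth, seeds, photosensitivity) and a
    thigmomorphogenetic safety factor (secondary growth). Forests evolve on
    circular islands through mutation and selection; storms prune branches
    with Weibull fracture probabilities. The package also provides the
    emergent-structure statistics (Strahler ratios, fractal dimension,
    tapering, Leonardo's rule, self-thinning effective numbers, weighted
    reduced-major-axis fits) and a closed-form analytical scaling model
    that predicts tree allometries from self-similarity and constant wind
    safety.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
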
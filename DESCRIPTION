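Package: arousalfe
Title: Free-Energy Models of Emotional Arousal Potential
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Variational free energy as a model of emotional arousal potential.
    Implements exact free-energy decompositions on finite discrete generative
    models (Kullback-Leibler divergence plus surprisal; Bayesian surprise plus
    inverse accuracy), conjugate Gaussian belief updating with known sensory
    variance, closed-form arousal quantities (information gain, uncertainty and
    free energy as quadratic functions of prediction error), staged two-batch
    forms with their large-sample limits, analytic sensitivity of the quadratic
    coefficients to prior and sensory variance, and reproducible
    Bayesian-updating simulations demonstrating convergence of uncertainty to
    the stimulus-source entropy (perceived complexity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
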
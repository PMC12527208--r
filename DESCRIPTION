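Package: headingci
Title: Contextual Causal Inference Models of Visual-Vestibular Heading Perception
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative modelling and model-based analysis of heading
    perception in a moving environment. Implements a family of Bayesian
    ideal-observer models that infer the lateral component of self-motion
    from vestibular input and from visual motion collected before and
    during self-motion, including a contextual causal-inference observer
    that arbitrates between "environment kept moving the same way" and
    "environment changed" interpretations. Provides a synthetic-experiment
    generator reproducing the factorial visual-vestibular design (three
    visual-motion contexts by five visual velocities by ten headings),
    Monte-Carlo/kernel-density model fitting with maximum a posteriori
    estimation and AIC comparison, heading-bias and regression analyses,
    an adaptive-weight diagnostic of nonlinear cue combination, and
    motion-cloud stimulus synthesis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
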
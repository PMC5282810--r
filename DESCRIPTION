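Package: krigdoe
Title: Kriging-Assisted Design of Experiments for Culture-Medium Optimization
Version: 0.1.0
Authors@R:
    person("Medium", "Optimization Lab", email = "krigdoe@example.org",
           role = c("aut", "cre"))
Description: Closed-loop, model-based design of experiments for optimizing
    microbial and microalgal culture media on parallelized microtiter-plate
    platforms. Provides two-level full and regular fractional factorial
    design generators with estimability guarantees, effect estimation with
    reference-well normalization and pooled-variance t tests, ordinary
    Kriging (Gaussian-process) surrogate modelling with anisotropic
    correlation lengths and a nugget for replicate noise, Expected
    Improvement batch proposals drawn by a delayed-rejection adaptive
    Metropolis sampler, and a synthetic ground-truth response surface that
    emulates a micro-photobioreactor so the whole pipeline can be exercised
    and tested in silico.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
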
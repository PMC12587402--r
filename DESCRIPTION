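Package: formubo
Title: Constrained Multiobjective Bayesian Optimization of Protein Formulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A closed-loop experimental-design toolkit for antibody formulation
    development. Gaussian-process surrogates with a Matern 5/2 kernel model
    three developability objectives (melting temperature Tm, diffusion
    interaction parameter kD, and retained monomer after agitation); NSGA-II
    searches the surrogate Pareto front under acid-base chemistry and
    osmolality constraints; an exploit/explore acquisition rule with
    Kriging-believer batching proposes batches of formulations per iteration.
    Includes the acid-base speciation solver that reconstructs buffer
    compositions from pH and acid fractions, measurement models for nanoDSF
    melt curves, DLS dilution series and agitation stress assays, a synthetic
    virtual laboratory for end-to-end testing, and campaign diagnostics
    (hypervolume traces, predictive mean absolute error, Spearman
    correlations).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
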
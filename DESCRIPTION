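Package: forageVI
Title: Simulation and Neural-Population Analysis of Concurrent
    Variable-Interval Foraging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying self-paced foraging on two concurrent
    variable-interval (VI) reward schedules, as used in freely moving
    primate experiments. Provides an event-driven simulator of latching
    Bernoulli reward availability with its closed-form availability
    probability, two strategy agents (a noisy win-stay/lose-switch
    threshold agent and a marginal-value-theorem agent) together with
    generalized matching-law diagnostics, construction of behavioral
    reward predictors (causally filtered reward ratio, waiting time,
    availability probability) and press-binned reward-prediction
    statistics, a synthetic generator of locomotion traces and mixed
    selectivity Poisson spiking populations with a planted belief-noise
    latent, neural preprocessing (rate binning and smoothing, press-locked
    tensors, engagement masking, locomotion decorrelation by orthogonal
    projection), a 51-column temporal basis expansion of task variables,
    sparsified canonical correlation analysis between task and neural
    spaces, and time-resolved cross-validated decoding of reward, choice
    and the next waiting time.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
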
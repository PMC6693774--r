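Package: gptrace
Title: Gaussian Process Inference and Experimental Design for Two-Photon Imaging Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers latent neural activity with calibrated uncertainty from
    irregularly sampled two-photon fluorescence observations using Gaussian
    process (GP) regression with a sparse variational inducing-point
    approximation. Provides input warping for non-stationary stimulus-driven
    responses, GP equality testing with Euler-characteristic bootstrap null
    distributions, statistical validation of hierarchical-clustering splits,
    GP-ANOVA stimulus-effect selection by likelihood-ratio testing, and
    uncertainty-guided (closed-loop) stimulus-parameter design. Includes a
    synthetic-data generator emulating spiral and linear scan sampling,
    chirp/sine/moving-bar stimuli and calcium-indicator kinetics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    ape,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
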
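Package: tracegan
Title: Conditional Adversarial Generation of Time-Aware Process Traces
Version: 0.1.0
Authors@R:
    person("Process", "Mining Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Generates privacy-preserving synthetic event logs (activity
    sequences with per-activity timestamps) with a conditional generative
    adversarial network. The generator is a non-autoregressive transformer
    encoder conditioned on total case duration; the discriminator is a
    time-aware multi-head self-attention network that attends jointly over
    activities, timestamp differentials, and pairwise time-interval
    matrices. Includes a multi-task context generator with homoscedastic
    uncertainty loss weighting, a three-part evaluation suite (statistical
    measures, a supervised realism scorer, and a consensus-workflow
    summary), and a seeded workflow simulator for fully self-contained
    testing. All neural components run on a small built-in reverse-mode
    automatic differentiation engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
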
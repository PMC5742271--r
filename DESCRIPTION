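Package: dyadrec
Title: Cross-Recurrence Analysis of Dyadic Movement Coupling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies temporal coupling between two interacting partners
    (e.g., a parent animating an object and an infant tracking it) from
    per-frame object-tracker bounding boxes. Converts trajectories into
    categorical movement-direction time series, computes diagonal-wise
    cross-recurrence lag profiles with shuffled and random-pairing
    baselines, quantifies coupling asymmetry with anisotropic
    cross-recurrence measures (laminarity, trapping time, maximum line),
    and fits the associated mixed-effects statistical layer. Includes a
    synthetic leader-follower trajectory generator with known ground truth
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    lme4,
    lmerTest,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
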
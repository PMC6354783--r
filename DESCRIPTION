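Package: neuroallom
Title: Normative Allometric Modelling of Limbic Structure Volume and Shape
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how subcortical structures (amygdala,
    hippocampus) scale with overall brain size, and for detecting group
    differences in regional volume and vertex-wise surface shape that are
    not explained by brain-size differences. Implements tiered normative
    log-log (allometric) regression with sex-term selection, three
    brain-size adjustment strategies for group contrasts (allometric
    deviation, normalization by division, linear covariation), mass-
    univariate vertex-wise surface allometry with FDR-gated model
    selection, Benjamini-Hochberg and Bonferroni corrected contrasts,
    spatial correlation of statistic maps, and a calibrated synthetic
    cohort generator emulating sex-chromosome-aneuploidy study designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
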
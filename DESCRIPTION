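Package: vibremg
Title: Antagonist Surface EMG Modulation Analysis for Focal Muscle Vibration Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-session (control vs. focal muscle
    vibration) crossover studies of antagonist muscle activity recorded with
    surface electromyography during cyclic joint movement. Implements the
    fixed preprocessing chain (Butterworth band-pass, rectification,
    non-overlapping RMS envelope), a baseline-noise activation threshold
    (mean plus three standard deviations of a pre-movement window),
    movement-cycle segmentation from the joint-angle signal, per-trial total
    RMS over the central cycles, post/pre RMS ratios, and the two statistical
    families used to analyse them: within-session linear mixed-model
    contrasts against baseline and between-session paired comparisons
    (Shapiro-Wilk gated paired t / Wilcoxon), each with Benjamini-Hochberg
    false-discovery-rate adjustment. A synthetic crossover-study generator
    with the same statistical structure makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    data.table,
    Rcpp,
    ggplot2,
    lme4,
    rlang,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    lmerTest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
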
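Package: spcr
Title: Single-Sample Pre-Disease State Detection from Expression Ranking Change
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects the pre-disease (critical-transition) state from a single
    gene-expression sample per time point. Each sample is scored against a
    normal-sample baseline by combining per-gene expression change with
    expression-ranking change; the top-m per-gene products are aggregated
    into a ranking score whose significant increase over its initial value
    is an early-warning signal. Includes threshold calibration from normal
    samples, time-course and stage-wise detection modes, candidate
    signaling-gene selection, ground-truthed synthetic-data generators (a
    latent-factor model planting a dynamic-network-biomarker module, and a
    small Michaelis-Menten stochastic regulatory network driven across a
    fold bifurcation), and delimited-text readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
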
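Package: ddmrd
Title: Droplet Digital PCR Quantification of BCR/ABL1 Minimal Residual Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification and interpretation of BCR/ABL1 transcript levels
    measured by droplet digital PCR (ddPCR) for minimal residual disease (MRD)
    monitoring in Philadelphia-positive acute lymphoblastic leukaemia.
    Converts well-level droplet counts to concentrations through the Poisson
    partition model with exact (Clopper-Pearson) confidence intervals, merges
    replicate wells by pooling partitions, applies droplet-count quality
    control, computes the target/control MRD ratio, and assigns
    positive / positive-non-quantifiable / negative calls under
    parameterised EuroMRD-style interpretation rules. Includes tools for
    limit-of-detection replicate-escalation experiments, assay specificity
    and reproducibility checks, paired-method concordance analysis
    (cross-tabulation, exact McNemar test, Pearson correlation), and a
    droplet-level synthetic data generator for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
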
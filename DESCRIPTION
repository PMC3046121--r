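Package: batchbench
Title: Simulation-Based Benchmarking of Batch-Effect Adjustment for Expression Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates gene-by-sample log2 expression matrices under a
    location/scale (L/S) batch-effect model with full ground truth, applies
    five batch-adjustment algorithms (gene-wise mean-centering, geometric
    ratio adjustment, parametric and non-parametric empirical-Bayes
    location/scale adjustment, and surrogate-variable adjustment), and scores
    them with principal variance component analysis (PVCA), replicate
    precision metrics (Pearson/ICC with Fisher z), fold-change accuracy
    metrics (Spearman correlation, signal-detection slope), and overall
    performance metrics (ROC-AUC with DeLong comparison, Matthews correlation
    coefficient). Includes an end-to-end benchmark runner producing a
    per-method report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    lme4,
    stats,
    utils
Suggests:
    pROC,
    sva,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
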
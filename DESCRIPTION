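Package: transcpm
Title: Transdiagnostic Connectome-Based Predictive Modeling of Memory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ridge-regularized connectome-based predictive modeling (rCPM) of
    latent behavioral phenotypes from multi-task functional connectomes.
    Builds Fisher-z connectivity matrices from node time series, constructs
    latent memory constructs by fold-restricted principal component analysis,
    selects edges by (partial) correlation with the phenotype, and fits a
    single ridge model over all selected edges from all tasks. Includes
    10-fold, leave-one-diagnostic-group-out and cross-dataset validation with
    permutation nulls, edgewise multivariate (MANOVA / Hotelling T2) analysis
    of diagnostic group differences with false-discovery-rate control,
    node/task/network contribution summaries, hypergeometric network-overlap
    testing, and a synthetic cohort generator with ground truth for
    calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
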
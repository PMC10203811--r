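Package: dmnsme
Title: Resting-State BOLD Amplitude and Subsequent-Memory Multimodal fMRI
    Analysis
Version: 0.1.0
Authors@R:
    person("dmnsme", "developers", email = "dmnsme@example.org",
           role = c("aut", "cre"))
Description: Tools for linking resting-state BOLD amplitude fluctuations
    to memory-encoding-related brain activity in the default mode network
    (DMN). Implements the percent amplitude of fluctuation (PerAF) and its
    global-mean-normalized variant (mPerAF) from band-pass filtered 4D
    BOLD series, a single-subject task GLM with an arcsine-transformed
    subsequent-memory parametric modulator, a voxel-wise multi-modal group
    GLM supporting voxel-wise imaging covariates with permutation max-T
    family-wise error control, recognition-memory scoring (confidence-rating
    ROC/AUC), ROI summarization, and Bayesian Pearson correlations. A fully
    seeded synthetic-data generator produces cohorts, rating tables, and 4D
    rest/task NIfTI images with known ground-truth effects so that every
    stage of the pipeline is testable without access to raw MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
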
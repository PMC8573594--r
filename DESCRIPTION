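Package: wmhda
Title: Domain Adaptation Workbench for White Matter Hyperintensity Segmentation
Version: 0.1.0
Authors@R: person("WMH", "Tools", email = "wmhda@example.org", role = c("aut", "cre"))
Description: A triplanar 2D U-Net ensemble for white matter hyperintensity (WMH)
    segmentation from FLAIR and T1-weighted brain MRI, together with five domain
    adaptation strategies (direct source transfer, layer-wise fine-tuning,
    unsupervised and semi-supervised domain-adversarial training with a gradient
    reversal layer, and iterative domain unlearning) and a voxel- and cluster-wise
    evaluation suite (Dice similarity index, voxel TPR/FPR, 26-connected cluster
    TPR/precision/F1, absolute log volume difference, paired permutation tests,
    feature-space domain-accuracy probes). Includes a seeded generator of synthetic
    two-domain FLAIR/T1 lesion cohorts for end-to-end benchmarking on CPU, and
    minimal NIfTI-1 input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
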
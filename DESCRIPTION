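Package: phmri
Title: Pharmacological fMRI Activation Mapping for Awake-Rodent BOLD Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for pharmacological fMRI (phMRI)
    in the awake rodent: global linear drift estimation and correction,
    Gaussian spatial smoothing, voxel-wise percent BOLD change with
    heteroscedastic (Welch) baseline-versus-window t-tests under
    Benjamini-Hochberg false discovery rate control and an amplitude
    threshold, atlas-based volume-of-activation summaries with
    Kruskal-Wallis group comparisons, composite activation maps, and
    circuit-level time courses analysed by mixed-design repeated-measures
    ANOVA with Dunnett many-to-one post-hoc tests. Includes a synthetic
    4D BOLD cohort generator with known ground truth for validating the
    pipeline, and NIfTI-1/CSV interfaces throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    multcomp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
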
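Package: vasoquant
Title: Quartile-Based Cerebrovascular Quantification from Power Doppler
    and Confocal Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the cerebral vascular network from two imaging
    modalities. Ultrafast power-Doppler frame ensembles are clutter-filtered
    by singular value decomposition, converted to power and decibel images,
    and summarized by intensity quartiles over a region of interest. 3D
    fluorescence vessel stacks are binarized by automatic (between-class
    variance) thresholding, labeled into connected components, and
    summarized by vessel volume fraction and volume-weighted quartiles.
    A gated statistical pipeline (Shapiro-Wilk normality gate selecting
    Student's t versus Mann-Whitney, and repeated-measures ANOVA with
    Bonferroni post hoc versus Friedman) compares genotypes and quartiles.
    A synthetic-data module generates ground-truthed vascular volumes,
    Doppler ensembles, and behavioral score tables so every stage can be
    verified by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    tiff,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
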
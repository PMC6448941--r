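Package: glucopreg
Title: Glucose Regulation in Pregnancy After Gastric Bypass: OGTT/IVGTT
    Indices, Cohort Simulation and Rank-Based Inference
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for assessing maternal glucose regulation from frequently
    sampled oral (3 h, 75 g) and insulin-modified intravenous glucose
    tolerance tests, as used in studies of pregnancy after Roux-en-Y gastric
    bypass. Computes fasting and dynamic insulin-sensitivity indices (QUICKI,
    OGIS, an IVGTT-based calculated sensitivity index), insulin-secretion
    indices (acute insulin response, AUC-ratio insulinogenic indices), the
    disposition index, a second-derivative glucose shape (variability) index,
    and clinical classifications (gestational diabetes screening thresholds,
    post-load hypoglycaemia). Provides rank-based small-sample inference
    (Brunner-Munzel), protected-LSD ANOVA, Spearman correlation with
    confidence intervals, hyperbolic sensitivity-secretion regression,
    propensity-score caliper matching, chained-equation imputation of sparse
    test timepoints, and a three-group synthetic-cohort generator with known
    ground truth for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: graphics, stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
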
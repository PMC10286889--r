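Package: ivimdce
Title: IVIM and Tofts-Model Quantitative MRI Biomarkers with Combination
    Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and estimation toolkit for quantitative MRI
    biomarkers of early-stage endometrial carcinoma. Generates synthetic
    diffusion-weighted (intravoxel incoherent motion, IVIM) and dynamic
    contrast-enhanced (DCE) image series with known ground truth, fits the
    bi-exponential IVIM model (segmented and full nonlinear least squares)
    and the standard Tofts pharmacokinetic model, aggregates parameter maps
    into volume-of-interest means, quantifies two-reader agreement by
    intraclass correlation, and runs the downstream biomarker statistics:
    normality-gated group comparisons, standardized-odds-ratio logistic
    models, ROC analysis with DeLong comparisons, bootstrap internal
    validation with backward elimination, calibration curves, and decision
    curve analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
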
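# ivimdce

Quantitative-MRI biomarker toolkit for early-stage endometrial carcinoma:
intravoxel incoherent motion (IVIM) diffusion modelling, Tofts-model
dynamic contrast-enhanced (DCE) pharmacokinetics, two-reader agreement,
and the biomarker-combination statistics used to separate TP53-mutant from
TP53-wild tumors and low-risk from non-low-risk disease.

## Who this is for

Imaging scientists who want a tested, scriptable re-implementation of a
typical multiparametric DWI/DCE tumor-characterization workflow — from raw
4-D image series to odds ratios, ROC comparisons and decision curves —
together with a synthetic-data generator that makes every stage testable
without patient data.

## The models

**IVIM.** The diffusion-weighted signal follows the bi-exponential model

    S(b) / S0 = (1 − f) · exp(−b·D) + f · exp(−b·D*)

with true diffusion coefficient `D` (mm²/s), pseudo-diffusion coefficient
`D*` of the microcirculation, and microvascular volume fraction `f`,
sampled at b = 0, 20, 40, 80, 160, 200, 400, 600, 800, 1000 s/mm². Two
estimators are provided: the classic segmented fit (high-b log-linear step
for `D`, intercept ratio for `f`, bounded 1-D least squares for `D*`, plus
a fixed-point refinement that removes the perfusion residue from the
high-b step) and a bound-constrained Levenberg–Marquardt fit of all four
parameters.

**Tofts.** Tissue gadolinium concentration obeys

    Ct(t) = Ktrans · ∫₀ᵗ Cp(τ) · exp(−Kep·(t − τ)) dτ,   Kep = Ktrans / Ve

driven by an arterial input function `Cp` (measured from an artery signal,
or a Weinmann/Parker population model). Dynamic spoiled-gradient-echo
signals are converted to concentration through the steady-state SPGR
equation, and `(Ktrans, Ve)` are fitted with an exact piecewise-linear
exponential convolution that is stable at the 9-second frame spacing of a
40-phase acquisition.

**Statistics.** Volume-of-interest means from two readers are assessed
with the two-way random-effects absolute-agreement ICC (F-distribution
confidence bounds, four-band classification) and averaged; group contrasts
use Shapiro–Wilk-gated t / Mann–Whitney tests and one-way ANOVA; per-1-SD
odds ratios come from univariate and entry-rule (p < 0.1) multivariate
logistic models; diagnostic performance uses empirical ROC curves with
DeLong variances and Youden cutoffs, DeLong tests against the combined
score, stratified bootstrap validation with backward elimination,
logistic-recalibration calibration curves, and decision-curve analysis.

## Worked example

```r
library(ivimdce)

protocol <- acquisition_protocol()          # 10-b DWI + 40-phase DCE @ 9 s
truth  <- ivim_params(D = 0.86e-3, Dstar = 44.35e-3, f = 0.0243, S0 = 1000)
noisy  <- add_rician_noise(simulate_ivim_signal(truth, protocol),
                           snr = 150, seed = 21)
fit_ivim_full(noisy, protocol)
#> IVIM full fit (converged, 16 iterations), rss = 495
#> IVIM params: D = 0.0008726 mm^2/s, D* = 0.03818 mm^2/s, f = 0.02558, S0 = 1005

cohort <- generate_cohort(default_cohort_spec("risk"), seed = 123)
report <- run_full_analysis(cohort, seed = 123)
report
#> Quantitative-MRI biomarker analysis report
#>   74 patients, parameters: D, Dstar, f, Ktrans, Ve, Kep
#>   [risk] combined model (D + f + Ktrans + Ve): AUC = 0.925; bootstrap AUC = 0.897 (0.857 - 0.927)
#>   [tp53] combined model (D + Ve + Kep): AUC = 0.869; bootstrap AUC = 0.830 (0.703 - 0.870)

report$roc$risk$combined
#> ROC: AUC = 0.925 (95% CI 0.869 - 0.981), n = 30/44
#>   Youden cutoff -0.1762: sensitivity 86.7%, specificity 84.1%
```

The noisy single-voxel fit recovers `D` within a few percent while `D*`
shows its well-known instability at tumor-like `f` (~2%). The cohort run
generates 74 synthetic patients whose per-group parameter distributions
match published group summaries, measures them with two correlated
"readers", and reports the full inferential cascade: here the multivariate
risk model combines D, f, Ktrans and Ve into a score whose in-sample AUC
(0.925) exceeds every constituent parameter, and bootstrap validation
(1000 stratified resamples, backward elimination bounded at p = 0.1)
shows modest optimism.

A thin command-line front end is included:

```sh
Rscript inst/cli/qmri.R cohort  --out cohort.csv --seed 123
Rscript inst/cli/qmri.R analyze --cohort cohort.csv --out results/
Rscript inst/cli/qmri.R run     --out run/        --seed 123
```

## Scope

The package starts from co-registered image series (or its own phantoms):
DICOM ingestion, image registration, ROI delineation and scanner-side
reconstruction are out of scope, as are Bayesian/tri-exponential IVIM
variants and the extended Tofts model. See the methods vignette
(`vignettes/methods.Rmd`) for the modelling assumptions, generator design
and known limitations.
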
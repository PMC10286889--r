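---
title: "Models, synthetic data, and design choices in ivimdce"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, synthetic data, and design choices in ivimdce}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivimdce)
```

`ivimdce` re-implements, as tested reusable code, a multiparametric MRI
workflow for characterizing early-stage endometrial carcinoma: intravoxel
incoherent motion (IVIM) diffusion modelling, standard-Tofts DCE
pharmacokinetics, two-reader volume-of-interest agreement, and a
biomarker-combination analysis (group tests, standardized-OR logistic
models, ROC/DeLong, bootstrap validation, calibration, decision curves).
Because no patient data ship with the package, every stage is exercised on
synthetic phantoms and synthetic cohorts with known ground truth. This
vignette records the modelling assumptions, the generator design, the
numerical choices, and what the passing test suite does and does not
demonstrate.

## Signal models

### IVIM

A voxel's diffusion-weighted signal is modelled bi-exponentially,

$$\frac{S(b)}{S_0} = (1-f)\,e^{-bD} + f\,e^{-bD^*},$$

with $D$ the true (tissue-water) diffusion coefficient in mm²/s, $D^*$ the
pseudo-diffusion coefficient of capillary blood motion, and $f$ the
microvascular volume fraction. The default b-schedule is
0–1000 s/mm² in ten steps with five b-values at or above 200 s/mm², which
makes 200 s/mm² the natural perfusion/diffusion split: `b_threshold`
defaults to 200 and is configurable.

Two estimators are provided.

* `fit_ivim_segmented()` is the classic two-step fit — log-linear ordinary
  least squares on $b \ge$ `b_threshold` gives $D$ and an extrapolated
  intercept, $f$ follows from the intercept ratio, and $D^*$ from bounded
  one-dimensional least squares on the full curve with $(D, f)$ held
  fixed — plus a fixed-point refinement: the fitted perfusion component
  $f S_0 e^{-bD^*}$ is subtracted from the high-b samples and the first
  step repeated until the parameters stop moving. The refinement matters:
  at $D^* = 20\times10^{-3}$ mm²/s the perfusion compartment still
  contributes $\sim$0.2% of the signal at b = 200, which biases the plain
  two-step $D$ by several tenths of a percent; the refined iteration
  converges to the exact parameters on noiseless data (the suite verifies
  recovery to better than $10^{-4}$ relative over a
  $3\times3\times3$ grid of physiological parameters).
* `fit_ivim_full()` is a bound-constrained Levenberg–Marquardt fit of
  $(S_0, D, D^*, f)$ on the linear signal scale, initialized at the
  segmented estimate. Bounds are $D \in [0, 3\times10^{-3}]$,
  $D^* \in [3\times10^{-3}, 0.5]$ mm²/s, $f \in [0,1]$: physical ranges
  that also keep $D^* > D$ identifiable. Least squares is run on the
  linear (not log) scale everywhere except the high-b OLS step, because
  log-scale weighting would up-weight the noisiest high-b samples.

Magnitude-MRI noise is Rician: each simulated value $s$ becomes
$\sqrt{(s+n_1)^2+n_2^2}$ with $n_1, n_2 \sim N(0, S_0/\mathrm{SNR})$, so
SNR is defined on the unweighted signal. The suite checks the two
well-known consequences: parameter RMSE decreases with SNR, and the
relative error of $D^*$ dominates that of $D$ at moderate SNR — the
instability that makes $D^*$ a poor discriminator in practice.

### DCE and the Tofts model

Tissue concentration follows the standard (two-parameter) Tofts model

$$C_t(t) = K^{trans}\int_0^t C_p(\tau)\,e^{-K_{ep}(t-\tau)}\,d\tau,
  \qquad K_{ep} = K^{trans}/V_e,$$

without a plasma-volume term: only $K^{trans}$, $K_{ep}$ and $V_e$ are
analyzed downstream, and adding $v_p$ at 9-second temporal resolution
would be poorly identifiable anyway. $K_{ep}$ is never an independent
degree of freedom; every fit emits it as the ratio of the fitted
$K^{trans}$ and $V_e$ (the suite asserts the identity to machine
precision).

The convolution uses an exact exponential recursion that treats $C_p$ as
piecewise linear between frames. For frame spacing $\Delta$ and
$x = K_{ep}\Delta$ the update is

$$I_k = I_{k-1}e^{-x} + w_0\,C_p(t_{k-1}) + w_1\,C_p(t_k),$$

with closed-form weights $w_0 = (1-e^{-x}-xe^{-x})/(K_{ep}^2\Delta)$ and
$w_1 = (x-1+e^{-x})/(K_{ep}^2\Delta)$, switching to series expansions for
$x < 10^{-5}$. This is exact for constant or piecewise-linear inputs and
stable at the coarse $\Delta = 9$ s of the default 40-phase protocol; the
constant-input closed form is matched to better than $10^{-6}$ in the
tests. During development this oracle caught a transposed weight, which
is exactly the kind of defect trapezoid-only testing misses.

Signal conversion assumes a spoiled gradient echo in steady state,

$$S = M_0 \sin\alpha \frac{1-E_1}{1-\cos\alpha\,E_1},
  \qquad E_1 = e^{-TR/T_1},$$

with fast-exchange linear relaxivity $1/T_1(t) = 1/T_{10} + r_1 C(t)$.
Defaults: $TR = 3.5$ ms, $\alpha = 15°$, $r_1 = 4.5\,$s⁻¹mM⁻¹
(gadopentetate at 1.5 T), tissue $T_{10} = 1400$ ms, blood
$T_{10} = 1440$ ms, hematocrit 0.42 — all configurable, since none are
recoverable from a vendor workstation's undisclosed conversion. The
inverse conversion fixes $M_0\sin\alpha$ from the mean of the
`n_baseline` (default 3) pre-contrast frames and solves $E_1$ frame-wise
in closed form; signals above the SPGR-attainable range are flagged and
clamped rather than propagated as negative $T_1$.

The arterial input is either measured (converted from an artery signal
and divided by $1-\mathrm{hct}$) or a population model: a Weinmann-type
bi-exponential (default, analytically convenient and monotone after the
bolus) or the Parker mixture (two Gaussian first-pass peaks plus a
sigmoid-modulated washout) at its published coefficients for a
0.1 mmol/kg dose, scaled linearly in dose. The default dose, 0.1 mmol/kg,
corresponds to 0.2 mL/kg of a 0.5 mmol/mL gadolinium chelate. A measured
patient-specific AIF is not reproducible offline, so the population curve
stands in; fits against either are exercised by the forward/inverse
round-trip tests.

## The synthetic cohort generator

The generator's job is to produce 74-patient cohorts (44 low-risk /
20 intermediate / 10 high-risk; TP53 status typed in 46: 21 mutant,
25 wild, 28 missing) whose six VOI-mean parameters reproduce published
per-group summaries, so the downstream statistics run on realistic group
structure. Design points:

* **Marginals follow the reporting family.** Cells published as
  median (q1, q3) are right- or left-skewed; a plain log-normal cannot hit
  strongly log-asymmetric triples (for the low-risk $K^{trans}$ cell it
  misses q3 by ~13%), so each skewed cell uses a *two-piece log-normal*
  whose quantile function matches q1, the median and q3 exactly at
  population level. Cells published as mean ± SD use a normal truncated
  to physical bounds, with the underlying location and scale solved
  numerically so the *truncated* moments equal the targets (naive
  truncation at zero would shed ~3% of the SD for the lowest cells).
  Extreme tails of the skewed cells are winsorized at the 0.5th/99.5th
  percentile: the published IQRs imply log-scale spreads up to ~1.25,
  whose raw tails occasionally produce physically absurd values
  ($K^{trans} > 12$ min⁻¹) without affecting any quantile target.
* **Dependence via a Gaussian copula.** A common multivariate normal is
  transformed through the marginal quantile functions. The default copula
  is the identity (the real inter-parameter covariance is unpublished);
  a "family" option puts 0.3 between the same-family perfusion pairs
  ($D^*$–$f$ and $K^{trans}$–$V_e$), and any valid matrix can be
  supplied.
* **$K_{ep}$ is derived, not drawn.** Each patient's (and each
  reader's) $K_{ep}$ is recomputed as $K^{trans}/V_e$, preserving the
  ratio identity row-wise. Consequently the published $K_{ep}$ cells are
  *not* generator targets: with unknown $K^{trans}$–$V_e$ covariance the
  ratio's median cannot be pinned independently, and the generator makes
  no attempt to resolve that.
* **Two readers.** Each patient's latent parameter vector is measured by
  two synthetic readers as latent value plus independent Gaussian noise,
  clamped to physical ranges, with $K_{ep}$ recomputed per reader. The
  noise scale defaults to 0.42 of each parameter's robust (IQR-based)
  between-patient spread, which targets a two-reader ICC around 0.85 —
  the "excellent" band typical of VOI-mean agreement studies; the
  realized ICC varies by parameter because the skewed cells' variance is
  tail-dominated.
* **TP53 overlay.** On risk-stratified cohorts, the 46 typed patients are
  chosen at random and the 21 mutants sampled without replacement with
  weights increasing in $z(K^{trans}) + z(K_{ep}) - z(D)$, giving the
  TP53 contrast its reported direction (higher transfer constants, lower
  $D$ in mutants) without fixing its magnitude. TP53-group *marginal*
  fidelity is checked on a separate two-group specification drawn
  directly from the TP53 cells.
* **Screening roster.** A 114-candidate roster carries six boolean
  exclusion attributes (non-carcinoma diagnosis, FIGO ≥ II, prior
  radio/chemotherapy, incomplete sequences, inadequate image quality,
  treatment elsewhere) assigned to exactly 7, 16, 4, 3, 6 and 4 distinct
  records, so the eligibility filter enrolls exactly 74.

What passing tests show — and do not. The generator reproduces *group
summaries* under a *chosen* dependence structure; it does not reproduce
the unknown joint distribution of real tumors, scanner artifacts, ROI
delineation variability, or any association between imaging and the
untyped TP53 patients. Statistics computed on these cohorts therefore
validate the *machinery* (correctness of ICC, ROC, bootstrap, and so on)
and qualitative structure (the combined model dominating its
constituents), not the published patient-data-dependent effect sizes:
printed AUCs or p-values from the source cohort are expressly not targets.

## Statistical pipeline choices

* **Normality gate.** Shapiro–Wilk at $\alpha = 0.05$ on both groups
  routes a comparison to the independent-samples t-test (Welch by
  default; the pooled-variance variant is an option) or to the
  Mann–Whitney U test with normal approximation, continuity and tie
  correction (exact enumeration when $\min(n_1,n_2) \le 8$ and no ties).
  Summaries follow the test family: mean ± SD vs median (q1, q3). The
  suite verifies nominal type-I error (within [0.03, 0.07] at
  $\alpha = 0.05$ over 2000 null simulations, n = 30/group) and the exact
  identity between the U statistic and the ROC area.
* **ICC.** Two-way random-effects, absolute-agreement, single-measure
  ICC(A,1) — the standard choice for interchangeable readers — computed
  from the ANOVA mean squares, with F-distribution confidence bounds
  (asymmetric, as agreement CIs should be). Bands: poor < 0.40 ≤ fair
  < 0.60 ≤ good < 0.75 ≤ excellent. ICC is computed on per-patient VOI
  means, not voxelwise.
* **Logistic models.** All predictors are z-scored, so odds ratios are
  per 1 SD. Candidates enter the multivariate model when their univariate
  p-value is below `entry_p` (default 0.1); near-collinear candidate sets
  abort with the offending pair named. Separation is flagged (huge Wald
  SE) rather than silently reported as an astronomical OR.
* **ROC.** Empirical curve over all distinct thresholds
  ("score ≥ threshold" positive), AUC by the rank formula (ties ½), CI
  from the DeLong placement-value variance, cutoff by Youden's J with
  ties broken toward higher specificity. Single-parameter scores are
  oriented by the sign of the univariate logistic coefficient and the
  orientation recorded; the combined score is the multivariate linear
  predictor. DeLong tests between correlated curves use the paired
  placement covariance.
* **Bootstrap validation.** 1000 resamples (default), stratified by
  outcome so no resample is degenerate, with backward elimination inside
  each resample (drop the largest-p predictor while any $p \ge$ the 0.1
  bound), each resample's model scored on the original table; reported
  as mean AUC with a percentile 95% interval and per-predictor selection
  frequencies. Fixed default seed 123 makes reports bit-reproducible.
* **Calibration and decision curves.** Equal-frequency bins (default 10)
  of mean predicted vs observed rate plus logistic recalibration
  (intercept/slope on the logit of predictions, and the
  calibration-in-the-large offset intercept). Net benefit is
  $TP/n - (FP/n)\,p_t/(1-p_t)$ against treat-all and treat-none
  references; thresholds strictly inside (0, 1).
* **Multiplicity.** Raw p-values throughout; no multiple-testing
  correction is applied, and missing TP53 labels are handled
  complete-case.

## Numerical and engineering choices

* Nonlinear fits use bounded Levenberg–Marquardt (`minpack.lm::nls.lm`,
  `ftol = ptol = 1e-15`); non-convergence returns the best iterate
  flagged `converged = FALSE` rather than an error, and map fitting
  records a per-voxel quality flag. Out-of-mask voxels are `NaN`.
* All generators funnel randomness through an internal seed guard that
  restores the caller's RNG state, so fixed seeds give bit-identical
  phantoms, cohorts and reports without clobbering a session's stream.
* Images travel as NIfTI-1 with JSON sidecars (b-values or frame times,
  cross-validated against the fourth dimension); the pipeline writes
  uncompressed `.nii` so artifact hashes are byte-stable. Cohort CSVs use
  conventional display units ($D$, $D^*$ in $10^{-3}$ mm²/s, $f$ in
  percent) and are converted to SI internally; label enumerations and the
  two-rows-per-patient structure are enforced on read.
* The `run_pipeline()` manifest records the seed, a canonical-JSON config
  hash, per-stage status/timings and the md5 of every artifact; two runs
  of the same configuration produce identical hashes.

Problem sizes in the shipped tests and acceptance script were chosen to
keep a full check run in the order of a minute on one core while leaving
Monte-Carlo margins well clear of their thresholds: 27-point IVIM and
9-point Tofts recovery grids, 2000 null simulations for test calibration,
5000-replicate bootstrap for the DeLong variance cross-check, cohorts of
10,000 per group (summaries averaged over three seeds, since single-seed
quartiles of the heavy-tailed cells carry 1–2% sampling noise) for
generator fidelity, and 50 seeded 74-patient cohorts for the
combined-model dominance property.

## Known limitations

* One open reporting question is inherited deliberately: the published
  group summaries print $f$ in percent at values around 1.6–2.4, an order
  of magnitude below typical tissue perfusion fractions; the generator
  reproduces the printed numbers as given rather than reinterpreting
  them.
* The segmented fitter's refinement assumes the bi-exponential model is
  exact; under model mismatch (e.g. kurtosis at high b) it inherits the
  usual IVIM biases.
* The population AIF is not a substitute for a measured patient AIF when
  absolute $K^{trans}$ values matter; only relative/group analyses should
  be read off population-AIF fits.
* No B1/flip-angle correction, bolus-arrival estimation beyond the
  baseline convention, extended-Tofts term, tri-exponential or Bayesian
  IVIM variants, DICOM ingestion, registration, or survival analysis.
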
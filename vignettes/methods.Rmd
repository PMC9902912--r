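---
title: "Methods: target detection, clutter statistics and clinical models for spatially registered prostate MP-MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: target detection, clutter statistics and clinical models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srmpnomo)
```

## The problem and the modeling idea

Multi-parametric prostate MRI acquires several co-registered modalities —
T1 before and at maximum contrast, T2, the apparent diffusion coefficient
(ADC), high-b diffusion, and dynamic contrast-enhanced (DCE) series — of
the same anatomy. Once the modalities are resampled onto a common grid
(1 × 1 mm in-plane, 6 mm slice spacing), every voxel becomes a spectral
vector $x \in \mathbb{R}^B$ rather than a scalar, and tumor assessment
becomes a target-detection problem of the kind long studied in
hyperspectral remote sensing. This package implements that pipeline:
detect tumor voxels, summarize the detection as three per-patient imaging
features — shape (eccentricity), spectral separation from normal tissue
(signal-to-clutter ratio, SCR), and volume — and feed those features into
a logistic model whose output is rendered as a nomogram and evaluated with
ROC and decision-curve analysis against a binary clinically-significant-
cancer (CsPCa) label derived from Gleason grading (patterns of at least
4+3 are significant; 3+4 and below are not).

## Background ("clutter") model

Normal prostate tissue is summarized by the mean $\mu_b$ and sample
covariance $\mathrm{CM}$ (denominator $n-1$) of the voxel vectors inside
the normal-prostate outline. The covariance corrects for correlations
among bands (ADC and high-b diffusion are strongly coupled, for example)
so that correlated evidence is not double-counted. Everything downstream
needs $\mathrm{CM}^{-1}$, and the package exposes four inverses behind one
seam (`inverse_spec()`):

* **full** — the dense inverse; errors with the condition number when the
  covariance is numerically singular;
* **pc_filtered(k)** — drop the $k$ smallest-eigenvalue principal
  components and invert on the retained span,
  $\sum_{i \le B-k} \lambda_i^{-1} v_i v_i^\top$. Noise concentrates in
  the low-variance components, so truncation suppresses noise
  amplification. The reported "3PC"/"4PC" SCR variants remove the 3 or 4
  smallest components and retain the large ones;
* **regularized($\gamma$)** — shrink toward the scaled identity,
  $\mathrm{CM}(\gamma) = (1-\gamma)\,\mathrm{CM} +
  \gamma\,\tfrac{\operatorname{tr}\mathrm{CM}}{B} I$;
* **modified_regularized($\gamma$)** — shrink toward
  $\operatorname{diag}(\mathrm{CM})$.

Both shrinkage targets preserve the trace exactly and give a symmetric
positive-definite matrix for any $\gamma \in (0,1]$ when the diagonal is
positive.

**Choosing $\gamma$.** A well-specified Gaussian background has squared
Mahalanobis distances $d_i^2 = (x_i-\mu_b)^\top \mathrm{CM}(\gamma)^{-1}
(x_i-\mu_b)$ distributed $\chi^2_B$. `select_gamma()` scans
$\gamma \in \{0, 0.01, \dots, 1\}$ and picks the value minimizing the
Kolmogorov–Smirnov distance between the empirical $d_i^2$ and
$\chi^2_B$, ties to the smallest $\gamma$ — i.e. the shrinkage that makes
the background look most multivariate-normal. Because the distances are
evaluated on the same voxels that produced $\mathrm{CM}$, a clean,
well-conditioned Gaussian background selects $\gamma^* \approx 0$ (the
sample covariance already studentizes its own data); positive shrinkage
is selected when the covariance is rank-deficient or ill-conditioned, in
which case the singular $\gamma = 0$ grid point is skipped with a notice.
This in-sample behavior is a property of the chosen criterion and is
asserted in the tests.

**SCR.** The signal-to-clutter ratio of a tumor signature $s$ is
$\mathrm{SCR} = \sqrt{(s-\mu_b)^\top \mathrm{CM}^{-1} (s-\mu_b)}$ under
whichever inverse is requested; the squared variant is exposed as an
option. Removing principal components can only remove non-negative terms
$\lambda_i^{-1}(v_i^\top d)^2$, so SCR is non-increasing in the number of
removed components — a property-tested invariant.

## ACE detection and blob shape

The adaptive cosine estimator scores each masked voxel by

$$\mathrm{ACE}(x) = \frac{\left[(s-\mu_b)^\top \mathrm{CM}^{-1}
(x-\mu_b)\right]^2}{\left[(s-\mu_b)^\top \mathrm{CM}^{-1}(s-\mu_b)\right]
\left[(x-\mu_b)^\top \mathrm{CM}^{-1}(x-\mu_b)\right]},$$

the squared cosine between voxel and signature in covariance-whitened
coordinates: 1 when whitened-collinear, 0 when orthogonal, and bounded in
$[0,1]$ for any positive semi-definite inverse (Cauchy–Schwarz). A voxel
exactly at $\mu_b$ scores 0 by convention. Voxels above a strict
threshold $\tau$ are grouped into connected components; 26-connectivity
is the default (corner-touching voxels merge — conservative at 6 mm slice
spacing) with 6-connectivity available. Components are labeled in scan
order, so labeling and the largest-blob tie-break (maximum voxel count,
then smallest label) are deterministic. By reporting convention the shape
feature uses $\tau = 0.45$ on the largest blob and the volume feature
uses $\tau = 0.65$ summed over all blobs; volume is voxel count times
voxel size.

**Eccentricity.** Blob shape comes from the second-central-moment
(scatter) matrix of the blob's voxel coordinates in physical mm (so 6 mm
slices weigh in correctly). Its eigenvalues scale with squared semi-axes:
the largest, $l_k$, tracks the major axis and the second, $s_k$, the
transverse moment — note a true mechanical inertia tensor would invert
this ordering, which is why the scatter matrix is used. Eccentricity is
$E_k = \sqrt{1 - s_k/l_k}$, reproducing the classical ellipse formula
$\sqrt{1-b^2/a^2}$ and the endpoints 0 (sphere) and 1 (line); a
single-voxel blob is 0 by convention, and the normalized difference
$(l-s)/(l+s)$ is available behind a flag. Eccentricity is computed in
3-D; a per-slice 2-D variant would be a different (unimplemented)
convention.

## DCE washout

The DCE series tracks tracer concentration over a few hundred seconds.
For times beyond 50 s past the peak, tissue emptying is modeled as
$A e^{-k_{ep} t}$. `fit_washout()` takes the per-voxel argmax as the
peak, then fits log-concentration against time by linear least squares on
the window $t > t_{peak} + 50\,\mathrm{s}$ — exact for noiseless data,
deterministic, and scale-equivariant ($k_{ep}$ invariant, $A$ scales).
Voxels with a non-positive concentration in the window (noise can push
late samples below zero) fall back to bounded nonlinear least squares
with $k_{ep} \in [0, 10]\ \mathrm{min}^{-1}$, initialized from the
log-linear fit on the positive samples; voxels with fewer than 3 usable
post-peak samples are flagged missing rather than fitted. Whether the
original processing used a log-linear or nonlinear fit, and how
non-positive samples were treated, is not documented anywhere we know of;
this choice is the package's own and is isolated in one function.

## Clinical models

`fit_cspca_logistic()` is a maximum-likelihood logistic fit (IRLS,
tolerance $10^{-8}$, 100 iterations max). Because conventions for
goodness-of-fit reporting on a binary outcome differ, the fit reports,
all labeled: the squared correlation between outcome and fitted
probability as the headline $R^2$, the companion
$F = (R^2/k)/((1-R^2)/(n-k-1))$ with its F-distribution p-value
(the linear-probability-style summary), plus McFadden and Nagelkerke
pseudo-$R^2$ and the likelihood-ratio $\chi^2$ p-value. Complete
separation is detected per variable and reported as an error naming the
separating variable rather than returning a divergent fit.

**ROC.** The empirical ROC sweeps all thresholds; AUC is the trapezoid
integral, identical to the Mann–Whitney statistic with ties counted one
half (property-tested against exhaustive pair counting). The 95% CI uses
DeLong's variance by default, with a seeded stratified bootstrap as an
option.

**Nomogram.** With reference value $\mathrm{ref}_i$ the end of each
variable's observed range minimizing $\beta_i x$ (so points are
non-negative), scale $M = \max_i |\beta_i| \cdot \mathrm{range}_i$,
points $100\,\beta_i (x-\mathrm{ref}_i)/M$, and risk
$\operatorname{logit}^{-1}(\eta_{\min} + MT/100)$ at total points $T$,
the round trip through the points scale reproduces the model probability
exactly up to floating point — well inside the 0.005 documented
tolerance, which budget is left for reading values off tabulated axes.

**Decision curves.** At threshold probability $p_t$ a patient is called
positive when the predicted probability is at least $p_t$; net benefit is
$\mathrm{NB}(p_t) = \mathrm{TP}/N - (\mathrm{FP}/N)\,p_t/(1-p_t)$, with
treat-all $\pi - (1-\pi)p_t/(1-p_t)$ and treat-none 0 as references, on
the default grid $0.01$–$0.99$ step $0.01$. Univariate companion curves
are built from single-feature logistic fits. No strategy can exceed the
prevalence $\pi$; the model curve is not asserted to dominate the
references (that is an empirical finding, not an identity).

**Study protocol.** `run_study()` fits seven reported variable subsets on
all patients and carries three of them through the train/test protocol:
training on even enrollment numbers, testing on odd (1-based numbering —
the convention is assumed, not documented by the protocol), scoring test
patients with frozen training coefficients (asserted by identity of the
coefficient vector before and after scoring).

## The synthetic cohort generator

The generator exists so that every stage is testable without patient
data. What it emulates:

* a prostate ellipsoid (default semi-axes 22 × 17 × 15 mm) rasterized at
  1 × 1 × 6 mm;
* a multivariate-normal background with plausible band means and an
  AR(1)-correlated covariance (correlation $0.4^{|i-j|}$, band SDs
  roughly 10–20% of the means), matching the normality assumption the
  shrinkage criterion is built on; a multivariate-t option
  (`background_df`) provides a heavier-tailed robustness variant;
* seven bands: the six named modalities plus one spare channel. The
  acquisition convention this mirrors names six modalities yet carries
  seven components; the spare channel stands in for the unnamed seventh
  and carries no tumor contrast;
* a prolate tumor ellipsoid with volume uniform on 0.5–3 cc and
  major:transverse axis ratio uniform on 1.15–3.5 (true eccentricity
  $\sqrt{1-1/q^2}$, about 0.49–0.96). The major semi-axis is capped so
  the tumor fits inside the organ — large tumors become rounder, and a
  volume too large for even a sphere raises an error. Tumor voxels add a
  per-patient scaled spectral contrast (darker T2/ADC, brighter
  diffusion/enhancement), the scale uniform on 0.6–1.8, which spreads the
  true SCR across patients;
* per-voxel DCE decay series via `simulate_dce_series()` (gamma-variate
  rise purely to give the peak-finder something realistic; only the decay
  is contractual). In the hypercube itself the washout band is generated
  as a correlated Gaussian band like the others, while the drawn
  `true_kep` drives the optional time-series simulation;
* CsPCa labels drawn Bernoulli from a logistic model on the TRUE
  generator-side features with default coefficients
  $(\beta_0, \beta_{Ecc}, \beta_{SCR}, \beta_{Vol}) =
  (-19.5, 9.0, 1.7, 2.5)$, chosen once so the oracle AUC (computed from
  the generating probabilities) sits near 0.9 at prevalence near one
  half. Using true rather than measured features means pipeline
  measurement error attenuates the recovered AUC — intended, so that
  recovery tests measure the pipeline against an honest upper bound.

Reproducibility: per-patient seeds derive from the cohort seed by a fixed
counter ($\mathrm{seed} + 104729\,i \bmod 2147483629$), labels use the
counter-0 stream, so identical parameters and seed give byte-identical
cohorts and any single patient can be regenerated alone.
`simulate_truth_table()` replays only the truth draws of the same
streams — it matches `simulate_cohort()`'s truth table exactly and
supports large-sample label-model experiments without rasterizing images.

What the generator does **not** emulate: scanner artifacts, motion, bias
fields, partial-volume effects, non-ellipsoidal or multi-focal tumors,
spatial autocorrelation of background texture, or registration error.
Passing recovery tests therefore demonstrates correctness of the
algorithmic chain under the model's own assumptions, not clinical
performance on real cohorts; published discrimination figures from real
25-patient data are not reproducible from this package and are not
targets of its tests.

## Numerical choices and problem sizes

* Strict thresholds ($> \tau$) everywhere; thresholds 0.45/0.65 by
  reporting convention.
* The detection inverse defaults to the full covariance inverse — the
  synthetic background supplies thousands of voxels for a 7-band
  covariance, so conditioning is excellent; filtered/regularized inverses
  remain one argument away for noisy covariances (the PC-filtered
  detector's null distribution in the retained subspace has a noticeably
  fatter tail, which inflates false-alarm volume).
* Resampling: linear interpolation in-plane, nearest-slice along the
  slice axis (slices align by table position), rigid translation only.
* Eigen-decompositions via symmetric `eigen()`; whitening via Cholesky;
  covariance inversion errors rather than silently pseudo-inverting.
* Recovery experiments run at cohort size 200 (detection end-to-end) and
  2000 (label-model coefficients, truth-level only), which keep the whole
  suite comfortably within a desk-scale run while leaving standard errors
  small relative to the asserted tolerances.

## Known limitations

* The SCR normalization and the $\gamma$-selection statistic follow the
  package's reconstruction (Mahalanobis square root; KS-to-$\chi^2_B$);
  both sit behind `inverse_spec()`/`select_gamma()` so an alternative
  convention can be swapped in without touching callers.
* Eccentricity is 3-D; a 2-D per-slice convention would differ on thick
  slices.
* No PSA, age, or radiologist scoring enter the models by design; no
  calibration-curve analysis; the only data split is the even/odd
  protocol.
* DICOM ingestion and deformable registration are out of scope; real
  data enters as 4-D NIfTI plus a mask.
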
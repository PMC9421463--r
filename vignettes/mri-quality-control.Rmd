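---
title: "Methods: semi-automatic QC for multi-site MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-automatic QC for multi-site MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scanqc)
```

This vignette is the package's account of its methods: the feature
definitions, the statistical models and their assumptions, the synthetic
generator's design, the numerical choices, and what the test suite does and
does not establish about real data.

## The QC problem

Multi-centre MRI studies pool scans from scanners that differ in vendor,
field strength, coil and protocol. Image-quality features therefore have
*site-dependent* distributions: a perfectly good scan from a noisy scanner
can look like an outlier against the pooled cohort. The workflow implemented
here (a) computes scalar QC features per scan, (b) standardises them within
site, (c) flags the most deviant fraction per site for visual review
alongside a matched random sample of non-flagged scans (to estimate the
false-negative rate of the flagging itself), and (d) quantifies which
features actually predict the visual verdicts.

## Structural features (T1w, 12 features)

Tissue statistics are probability-weighted by default: with weights
$w_i$ (the tissue probability at voxel $i$), $\mu = \sum w_i x_i / \sum w_i$
and $\sigma^2 = \sum w_i (x_i-\mu)^2 / (\sum w_i - 1)$, which reduces to the
ordinary sample mean/SD for binary maps (hard-mask mode is available via
`weighting = "mask"`). Background voxels are those with brain-probability
sum below 0.05, excluding a 2-voxel frame at the image border; the tissue
binarisation threshold defaults to 0.5. The panel:

| feature | domain | definition |
|---|---|---|
| SNR | noise | $\mu_{WM}/\sigma_{WM}$ |
| CNR | noise | $|\mu_{GM}-\mu_{WM}| \big/ \sqrt{\sigma_{GM}^2+\sigma_{WM}^2+\sigma_{bg}^2}$ |
| CJV | inhomogeneity | $(\sigma_{WM}+\sigma_{GM}) / |\mu_{WM}-\mu_{GM}|$ |
| FBER | inhomogeneity | median(foreground$^2$) / median(background$^2$) |
| AI_perc | asymmetry | $100 \cdot \mathrm{mean}_{brain}\, |I - I_{flip}| / ((I+I_{flip})/2 + \varepsilon)$ |
| IQR | inhomogeneity | composite rating surrogate, see below |
| CSF_k | descriptives | excess kurtosis of CSF intensities |
| WM2MAX | inhomogeneity | $\mu_{WM} / P_{99.95}$(whole image) |
| GM/WM/CSFfrac | descriptives | tissue volume fractions of brain volume |
| EFC | descriptives | entropy-focus criterion of the whole image |

The left–right flip axis for AI_perc comes from the orientation label of the
volume (the axis labelled L/R), and $\varepsilon = 10^{-6} P_{99}$ of brain
intensities guards the division. Contrast below
$10^{-6}(|\mu_{WM}|+|\mu_{GM}|)$ makes CJV undefined; it is reported missing
with a warning rather than unbounded.

**IQR surrogate.** The "image quality rating" produced by common
segmentation toolboxes is an unpublished composite, so the package ships a
fully specified surrogate: two sub-scores — the noise-to-contrast ratio
$\sigma_{WM}/|\mu_{WM}-\mu_{GM}|$ and a bias estimate, the coefficient of
variation over WM of the image smoothed with a wide Gaussian
(default $\sigma = 6$ voxels) — are each mapped through a fixed logistic
$(u-0.1)/0.05$ to $(0,1)$ and combined as an equal-weight RMS. The logistic
centre/scale were fixed a priori so that typical clean phantoms (ratios
$\approx 0.03$–$0.08$) land on the lower shoulder and degraded scans
saturate toward 1; the surrogate is monotone in both noise and bias
amplitude, which the test suite asserts. It is *not* numerically comparable
to any toolbox's rating — only its domain behaviour is.

**Open reconstruction.** Only eight of the twelve structural features have
conventional names in the QC literature; the four descriptives
(tissue fractions and EFC) are this package's documented completion of a
12-feature panel.

## Functional features (BOLD, 17 features)

Framewise displacement follows the backwards-difference convention
$FD_t = |\Delta t_x| + |\Delta t_y| + |\Delta t_z| +
r(|\Delta r_x| + |\Delta r_y| + |\Delta r_z|)$ with head radius
$r = 50$ mm (configurable), $FD_1 = 0$, computed on raw (unfiltered) motion
parameters. The cohort rule excludes scans with mean FD above the group
mean + 2 sample SD; it requires at least 3 scans, and refuses to guess
otherwise. DVARS is the RMS volume-to-volume intensity difference within the
mask, normalised by the median in-mask intensity (making it scale-invariant);
temporal SNR is the voxelwise mean/SD over time averaged in the mask, and is
reported missing for zero-variance series rather than infinite. The
remaining panel members (temporal-SD P95, global-signal SD and drift,
spatial CV/FBER/EFC/asymmetry of the temporal mean, mask fraction, volume
count) complete a 17-feature panel whose membership is a documented
reconstruction — the panel *size* is the fixed contract, and
config-controlled membership beyond the motion/noise core is explicit in
`temporal_features()`.

## Diffusion features (20 features)

The tensor is fitted per voxel by ordinary least squares on
$\log S_i = \log S_0 - b_i\, g_i^\top D g_i$ (seven unknowns: six tensor
elements plus $\log S_0$), the standard log-linear estimator. Design
singularity is detected from the singular-value ratio (condition number
above $10^8$ is an error naming it). Nonpositive signals inside the mask are
clamped to the smallest positive signal of that voxel's series before the
log, and the clamp count is reported. Eigenvalues are *not* forced positive:
negative eigenvalues and pre-clip FA outside $[0,1]$ are exactly what the
`fa_outlier_pct` and `neg_eig_pct` QC features are designed to see; only the
released FA map is clipped. $FA = \sqrt{3/2}\sqrt{\sum_k(\lambda_k -
\bar\lambda)^2 / \sum_k \lambda_k^2}$, $MD = \bar\lambda$,
$AD = \lambda_1$, $RD = (\lambda_2+\lambda_3)/2$.

The 20-feature panel extends the five canonical members (z-translation,
motion-outlier percentage at a 1 mm RMS-displacement threshold — the
threshold is not standardised anywhere, so it is a documented configurable
default — mean SSE, FA outlier percentage, FA SD in WM) with per-axis motion
summaries, FD summaries, WM tensor-scalar descriptives and a b = 0 SNR.
With a single b = 0 volume (the emulated acquisition has exactly one) a
temporal SNR over b = 0 volumes does not exist; the feature then falls back
to the spatial mean/SD ratio of the b = 0 volume within WM, and is computed
temporally when two or more b = 0 volumes are present.

## Site-wise flagging

Z-scores use the site's sample SD; a feature constant within a site
contributes Z = 0 there (logged) instead of NaN. The ranking score is
$\sum_f |Z_{if}|$ over non-missing features, rescaled by
$n_{features}/n_{nonmissing}$ so partially missing scans stay comparable.
"Top 15%" is read as *per-site* selection — the phrase that motivates the
whole design is that feature distributions differ by site — with
`ceiling(fraction * n_site)` scans flagged per site, so small sites always
contribute at least one reviewed scan; a pooled `scope = "global"` mode
exists behind a switch. Boundary ties break lexicographically by scan id,
making the flag set a pure function of the data. All features carry equal
weight in the score, as no weighting scheme is part of the procedure.
Matched inliers are drawn without replacement, stratified by site to match
the flagged per-site counts; when a site runs out of inliers the shortfall
is topped up at random from other sites so the total matches
$\min(|flagged|, |inliers|)$. The review batch withholds statuses and is
ordered by a seeded shuffle; a sealed key reconstructs them after review.

## Feature informativeness

The proportional-odds model $P(Y \le k \mid x) = \mathrm{logistic}(\theta_k -
x^\top\beta)$ assumes common slopes across the cumulative logits and ordinal
labels poor < moderate < good. The likelihood is maximised on internally
z-standardised predictors by BFGS with the analytic gradient, then polished
by Newton steps on the analytic Hessian until the score norm is below
$10^{-8}$ — estimates therefore agree with IRLS binary logistic fits to
better than $10^{-9}$ when only two levels are present. Wald standard
errors come from the inverse analytic Hessian; coefficients, odds ratios,
95% CIs and p-values are reported on the raw predictor scale (the
standardised estimates are kept in the object). Missing data are handled
complete-case, once, upstream — elimination and model comparison always see
the same observations. Standardised coefficients above 25 in absolute value
abort with a complete-separation diagnosis rather than reporting meaningless
Wald intervals.

Backward elimination removes the single feature whose removal most decreases
AIC ($-2\ell + 2 \cdot \#\text{parameters}$) and stops when no removal
decreases it, so the reduced model's AIC never exceeds the full model's.
One property of this rule worth stating plainly: a truly uninformative
predictor is removed only when its likelihood-ratio statistic is below 2,
which for a $\chi^2_1$ variable happens with probability 0.843 — so plain
AIC elimination retains some pure-noise predictors by design, about one in
six. The model comparison is the likelihood-ratio test
$LR = 2(\ell_{full} - \ell_{reduced}) \sim \chi^2_{df}$ for nested models on
identical observations.

The covariate screen fits, per feature, one linear model on site
(categorical) + age + sex + MMSE + amyloid + APOE, reports marginal
F-tests (`drop1`), and Bonferroni-corrects across the full
feature × covariate family. The same three-step analysis applies unchanged
to the diffusion panel — there is no separate code path per modality.

## Synthetic cohorts

The generator is fully parametric so every ground truth is known by
construction; it deliberately does *not* attempt anatomical realism (no real
head geometry, no k-space simulation).

* **Structural**: nested-ellipsoid compartments (WM core, GM shell, CSF rim)
  on a 64³ grid by default; tissue means (CSF/GM/WM = 150/400/600, arbitrary
  units) scaled by per-site multipliers spread over 0.9–1.1; Gaussian noise
  (base SD 20) scaled by per-site multipliers 0.8–1.25; optional
  multiplicative low-order polynomial bias field and hemispheric intensity
  asymmetry. Corrupted scans (per `artifact_prevalence`) get noise × 4,
  bias + 0.3 and asymmetry + 0.05 — severe enough to shift several features
  by multiple within-site SDs, emulating the scans a visual reader would
  call poor.
* **Functional**: static ellipsoid + temporal Gaussian noise + linear drift,
  32³ × 100 by default; motion traces are random walks with translation step
  SD 0.02 mm (clean) vs 0.5 mm (corrupted) and rotation steps 2·10⁻⁴ vs
  5·10⁻³ rad, which places corrupted mean FD far above the clean population
  (the separation the mean-FD exclusion rule needs).
* **Diffusion**: signals $S = S_0 e^{-b\,g^\top D g}$ from a two-region
  tensor field — prolate (1.7, 0.3, 0.3)·10⁻³ mm²/s (FA 0.799) and oblate
  (1.1, 0.8, 0.8)·10⁻³ (FA 0.190) — under a 1 × b = 0 + 54-direction
  b = 1000 scheme (Fibonacci-sphere directions), with Rician (default) or
  Gaussian noise at b = 0 SNR 30.
* **Feature-level**: `simulate_qc_features()` draws cohorts directly in
  feature space (unit within-site SD, Gaussian per-site offsets, corrupted
  scans with `n_shifted = 3` features moved by `shift_sd = 4` SDs). This is
  the fast generator for flagging/screening studies; the image-level
  generators exercise the identical pipeline end to end at smaller sizes.

Everything is reproducible from one master seed; per-scan sub-seeds are
derived arithmetically and stay below $2^{31}$.

**What passing tests show — and don't.** The generator produces exactly the
artifact-to-feature couplings the pipeline is designed to catch; real
low-quality scans carry structured artifacts (spike noise, wrap-around,
reconstruction failures) whose feature signatures can be weaker or
different. Detection recall measured here is therefore an upper bound on
real-world recall, and the ordinal-model calibration results say the
*estimator* is correct, not that real visual labels follow a
proportional-odds law.

## Numerical and design choices

* Sample SDs (denominator $n-1$, or $\sum w - 1$ weighted) throughout.
* Quantiles use R's default (type 7) definition.
* Gaussian smoothing is separable with mirror boundaries, kernel truncated
  at $3\sigma$.
* Flag-boundary ties: lexicographic scan id. Uniform scores still flag the
  required count, with a warning.
* Scan-type rules match the series description first, then protocol name +
  image type; smallest priority wins; matching is case-insensitive. The
  shipped default table is a reconstruction of typical vendor naming, meant
  to be replaced per deployment.
* Completeness checking of a series needs an `expected_files` count; absent,
  it is skipped with a notice rather than guessed.
* Problem sizes in the tests and the acceptance script (e.g. 10³-voxel
  diffusion phantoms, n = 2000 ordinal cohorts, 100–500 simulation
  replicates) were chosen as the smallest sizes at which the asymptotic
  claims under test (coverage, Wilks calibration, recall) are stable.

## Known limitations

* Tissue segmentation, registration, realignment and distortion correction
  are out of scope: the package consumes their outputs (probability maps,
  motion traces).
* The IQR surrogate is not comparable to external quality ratings.
* The functional and diffusion panels beyond the canonical members are
  reconstructions with configurable membership; panel sizes (12/17/20) are
  the stable contract.
* The proportional-odds fitter has no penalised mode; separated data abort
  with an informative error.
* Phantoms are geometric, not anatomical; see the caveat above on
  generalising recall figures to real data.
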
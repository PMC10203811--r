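---
title: "Methods: resting-state amplitude, subsequent memory, and the voxel-wise multimodal GLM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resting-state amplitude, subsequent memory, and the voxel-wise multimodal GLM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmnsme)
```

## The scientific problem

The default mode network (DMN: medial prefrontal cortex, posterior
cingulate, precuneus, temporoparietal regions) deactivates during demanding
tasks, and in young adults stronger DMN activity during memory encoding
predicts later *forgetting*. In older adults this subsequent-memory
relationship is attenuated or even reversed. One way to ask whether this
reflects a generally reduced ability to modulate DMN activity is to compare,
in the same people, (i) the amplitude of spontaneous DMN BOLD fluctuations
at rest and (ii) the encoding-related DMN signal, voxel by voxel, while
controlling for structural covariates such as regional grey-matter volume
(GMV), hippocampal volume, total intracranial volume (TIV), and white-matter
lesion volume (WMLV).

This package implements that full analysis chain — amplitude maps, a
parametric subsequent-memory first-level model, and a voxel-wise multimodal
group GLM — together with a seeded synthetic-data generator so every stage
is testable without access to raw MRI.

## Resting-state amplitude: PerAF and mPerAF

For a voxel time series $y_1,\dots,y_n$ with mean $\mu$,

$$\mathrm{PerAF} \;=\; \frac{1}{n}\sum_{i=1}^{n}\frac{|y_i-\mu|}{\mu}\cdot 100,$$

the mean absolute BOLD deviation as a percentage of mean intensity. It is
scale-independent (multiplying the series by any positive constant leaves it
unchanged) and sign-free. `mPerAF` divides each voxel's PerAF by the global
mean PerAF over a normalization mask, so its mean over that mask is exactly 1.

The measure is computed on band-limited data (0.01–0.08 Hz by default, the
conventional low-frequency fluctuation band). Implementation decisions:

* **Filter.** Per-voxel linear detrend, then an ideal (rectangular)
  frequency-domain filter with in-band edge bins inclusive. An ideal filter
  is exactly reproducible and introduces no ringing-parameter choices; its
  known drawback (Gibbs ringing on broadband transients) is immaterial for
  an amplitude summary.
* **The mean $\mu$.** Band-passing destroys the mean BOLD intensity that the
  PerAF denominator needs, so `detrend_bandpass()` re-adds the raw series
  mean after filtering: deviations are band-limited, the denominator is the
  raw mean. This matches the intent of "fluctuation relative to mean signal
  intensity"; the upstream literature does not pin the convention down.
* **Degenerate voxels.** Voxels with non-positive mean or zero variance get
  PerAF 0 and a row in a QC table, rather than NaN propagation.
* **Normalization mask.** Brain mask intersected with voxels of nonzero
  PerAF (an "inclusive mask of active voxels"); overridable.

## Recognition memory: ratings, the arcsine modulator, and AUC

Memory is probed with 5-point recognition-confidence ratings
(1 = sure new … 5 = sure old). Two derived quantities:

* **Parametric modulator.**
  $\mathrm{PM}(x) = \arcsin\!\big(\tfrac{x-3}{2}\big)\cdot\tfrac{2}{\pi}$,
  mapping ratings to $[-1, +1]$ with PM(3) = 0. Relative to a linear
  recoding, the arcsine up-weights high-confidence responses; "undecided"
  contributes no subsequent-memory information.
* **AUC.** Cumulative hit and false-alarm proportions at the criteria
  $\ge 5, \ge 4, \ge 3, \ge 2$, closed at (0,0) and (1,1), integrated by the
  trapezoidal rule. This equals the tie-corrected Mann–Whitney statistic
  $U/(n_{old} n_{new})$ — a property the test suite asserts on 1,000 random
  tables. Memory scoring uses the 88 once-seen old items and 44 new items;
  the two pre-familiarized "master" images are excluded (they exist to
  anchor fMRI novelty contrasts, and whether the original analysis scored
  them is not stated).

## First-level model (subsequent memory effect)

The encoding run is modeled with a GLM: novelty and master boxcars (2.5 s
events) built on a microtime grid (16 bins per TR, reference bin 8),
convolved with a canonical double-gamma HRF, plus the novelty boxcar
weighted by the mean-centered PM, six motion regressors when available, a
discrete-cosine high-pass basis (128 s cutoff), and a constant. The SME map
is the estimate of the PM-modulated regressor: positive where stronger
responses predict remembering, negative where they predict forgetting.

Decisions:

* **HRF parameterization.** The kernel is specified by its stated shape:
  gamma-density *modes* at 6 s (response) and 16 s (undershoot), unit
  dispersions, undershoot ratio 1/6, 32 s support, peak-normalized. (SPM's
  `spm_hrf` parameterizes shape/rate as 6/1 and 16/1, putting the modes at
  5 s and 15 s; we follow the stated peak contract, same kernel family.)
* **PM centering.** PM is mean-centered across novel events before
  modulation, keeping the novelty main effect interpretable (the standard
  parametric-modulation convention).
* **OLS, not prewhitening.** Downstream analyses consume contrast
  *estimates*, which are unbiased under OLS with temporally correlated
  noise; first-level inference is never used. (The synthetic noise is white,
  so here OLS is also efficient.)

## Voxel-wise multimodal group GLM

The group design crosses age group and scanner into four cell indicators
(no intercept), adds scalar covariates that are group-wise mean-centered
and, where the model calls for group-specific slopes, split into young/old
columns (hippocampal volume, TIV, WMLV; age enters as a single group-wise
centered column), and adds voxel-wise imaging covariates (GMV, mPerAF):
per-subject 3D maps expanded into cell-specific columns and mean-centered
within cell at every voxel, making the design matrix voxel-dependent. The
canonical models are available from `default_model()`; the amplitude/SME
model has the 15 columns
`young_Skyra … older_Verio, HCvol_young, HCvol_old, TIV_young, TIV_old,
WMLV_young, WMLV_old, age, GMV_young_Skyra … GMV_old_Verio`.

Estimation is independent OLS per voxel; with no voxel-wise covariates this
reduces — bit-identically, by construction and by test — to a single
standard group GLM. Rank-deficient voxels (e.g. a locally constant
covariate) are masked out and counted, not imputed; pervasive deficiency
(> 50 % of voxels) aborts with diagnostics.

**Inference.** Random-field-theory FWE (as used by SPM) requires smoothness
estimation that is out of scope here; the package instead uses the
permutation maximum-statistic method: Freedman–Lane residual permutation
under the reduced model (nuisance = the null-space of the contrast),
optionally stratified (e.g. by scanner), with the observed labeling included
in the null distribution. The voxel-wise FWE p-value is the proportion of
permutations whose maximum t reaches the voxel's t; this is exact under
exchangeability, and a 500-dataset Monte-Carlo calibration in the test suite
checks the empirical FWER at $\alpha = .05$. Thresholded voxels are grouped
by 26-connectivity and clusters below the extent threshold ($k = 10$ by
default) are discarded. Because the error-control method differs from
random-field theory, critical values will not numerically match
RFT-derived height thresholds (e.g. $T = 4.88$ at comparable scale).
Two-sided questions are asked as two one-sided contrasts, matching the
field's separate positive/negative effect reporting.

## Bayesian Pearson correlations

`bayes_pearson()` reports the sample correlation $r$ and the Bayes factor
$BF_{10}$ for a nonzero population correlation $\rho$, using the exact
sampling density of $r$ given $\rho$ (a Gauss hypergeometric
${}_2F_1$ form, evaluated by series) integrated against a two-sided
stretched-beta prior on $\rho$. The default width $\kappa = 1$ — the default
of the common Bayesian software — makes the prior uniform on $(-1, 1)$.
Integration is adaptive quadrature; the test suite checks the engine against
an independent trapezoid-grid oracle whose ${}_2F_1$ comes from the Euler
integral representation. Results are prior-sensitive, so $\kappa$ is an
argument, and no multiplicity adjustment is applied across correlation
grids (Bayes factors are reported raw). $BF_{01} = 1/BF_{10}$ by
construction; $|r| = 1$ returns $BF_{10} = \infty$.

Published full-sample anchors reproduce to ~1 % (consistent with the
printed $r$ being rounded to three decimals); grid cells based on
neuropsychological subscores imply smaller effective samples and are not
used as anchors.

## The synthetic world

The generator's defaults *are* the stated study conditions:

| quantity | young | older | source of the default |
|---|---|---|---|
| n | 106 | 111 | published demographics |
| scanner (Verio/Skyra) | 58/48 | 64/47 | published demographics |
| sex (f/m) | 59/47 | 65/46 | published demographics |
| age (years) | 24.12 ± 4.00 in 18–35 | 67.28 ± 4.65 in 60–80 | published demographics (truncated normal) |
| recognition AUC | 0.82 ± 0.07 | 0.77 ± 0.07 | published behavioral summary |
| hippocampal volume (mm³) | 6890.91 ± 638.65 | 6453.07 ± 593.21 | published structural summary |
| TIV (mm³) | 1.5 × 10⁶ ± 1.5 × 10⁵ | same | field-realistic choice (adult TIV ≈ 1.4–1.6 L) |
| WMLV (mm³) | log-normal, median 500 | log-normal, median 3000 | field-realistic choice (lesion loads are right-skewed and rise steeply with age) |

Further choices, made once:

* **Ratings.** Equal-variance Gaussian signal detection with four equally
  spaced criteria centered on $d'/2$. $d'$ is calibrated by numerically
  inverting the *expected trapezoidal AUC of the binned ratings* (closed
  form from the category probabilities), so the expectation of the statistic
  the package actually computes equals the subject's target AUC; inverting
  the continuous-model AUC $\Phi(d'/\sqrt 2)$ would leave a small
  discretization deficit (~0.01–0.02 at AUC 0.8).
* **Rest series.** Exactly band-limited fluctuations synthesized in the
  frequency domain (random phases, flat in-band power), per-voxel SD scaled
  so expected PerAF equals the target amplitude
  ($E|y-\mu| = \sigma\sqrt{2/\pi}$ for Gaussian fluctuations), plus optional
  white noise. DMN amplitude defaults: 3.0 % (young) vs 2.4 % (older),
  SD 0.5, background 2.0 % — the ~20 % group difference mirrors the
  direction and rough size of the reported DMN group effect at rest.
* **Task runs.** 88 novel + 44 master trials of 2.5 s. The published trial
  arithmetic (jitter uniform on 0.70–2.65 s) cannot fit 132 trials into the
  206-scan run it describes (expected 551 s > 531 s), so jitter defaults to
  0.7 s + Exp(mean 0.56 s) truncated at 2.65 s (mean ≈ 1.26 s, expected run
  ≈ 500 s) — the original study used an unpublished "optimized" jitter
  distribution. True SME betas default to −1.0 (young) and −0.4 (older)
  signal units per PM unit: negative (DMN deactivation predicts
  remembering), weaker in the older group.
* **Rest–encoding coupling.** The young-only negative relationship between
  resting amplitude and SME is injected as a slope of the subject's true DMN
  SME beta on their DMN rest amplitude (`coupling_slope_young = -0.8`,
  older slope 0). In the end-to-end fixture (40 + 40 subjects, first-level
  noise SD 1, SME beta noise 0.25, subject amplitude SD 0.5) the expected
  per-voxel t of the young-negative contrast is ≈ 8 (slope × amplitude SD ≈
  0.4 SME units of signal per subject against a residual SD ≈ 0.32 over
  ~40 subjects), so a sensitivity ≥ 0.8 criterion is comfortably inside the
  design's power rather than balanced on its edge.
* **Seeds.** A master seed plus stable FNV-style hashing of
  `(master seed, subject_id)` gives per-subject seeds, so any single
  subject's images are reproducible in isolation.

**What a green test does not establish.** The generator emulates amplitude
structure, design timing, and covariate distributions — not head motion,
physiological noise, spatial autocorrelation, scanner drift beyond a linear
trend, susceptibility dropout, or vascular confounds of amplitude measures.
Recovery results certify the estimators against the stated model, not
robustness to real-data artifacts. Voxel-level results of the original
study (peak statistics and coordinates) depend on 217 subjects of raw MRI
and on RFT inference and are not reproducible at desk scale by design.

## Numerical conventions

* Ideal band-pass: in-band edge bins inclusive; DC handled by removing and
  re-adding the mean.
* Permutation p-values: $(1 + \#\{ \max T^* \ge t \}) / (n_{perm} + 1)$ via
  inclusion of the identity permutation; fixed seed ⇒ identical thresholds.
* Cluster connectivity 26; peaks reported in mm via the affine when one is
  supplied (1-based voxel indices internally, RAS mm externally).
* Contrast machinery accepts named weights matched to design columns;
  nuisance space for Freedman–Lane is the orthonormal null space of the
  contrast.
* ANCOVA group F is the type-III model-comparison F; Levene's check is run
  on model residuals (mean-centered variant).
* `hyp2f1` series converges for the arguments used ($a=b=1/2$,
  $c = n - 1/2 > a + b$); `bayes_pearson` falls back to $BF_{10}=\infty$
  at $|r| = 1$.

## Limitations

No slice-timing/realignment/normalization preprocessing (inputs are assumed
preprocessed), no physiological nuisance regression, no ALFF/fALFF, no
random-field theory or TFCE, no first-level t-maps, and no d′/criterion
estimation from the ratings. The NIfTI reader/writer covers the subset of
NIfTI-1 needed here (scalar dtypes, sform affines) and is not a general
neuroimaging I/O library.
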
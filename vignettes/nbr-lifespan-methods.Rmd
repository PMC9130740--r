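---
title: "Methods: modelling lifespan change in the negative BOLD response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling lifespan change in the negative BOLD response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbrlifespan)
```

## The scientific problem

During a unilateral motor response, the sensorimotor cortex contralateral
to the moving hand shows a positive BOLD response (PBR) while the
ipsilateral sensorimotor cortex (iSM1) and default-mode regions such as
the posterior cingulate (PCC) typically deactivate — a negative BOLD
response (NBR), widely interpreted as a haemodynamic correlate of
inter-hemispheric inhibition. Across the adult lifespan the iSM1 NBR
shrinks in magnitude and spatial extent and its haemodynamic response
(HR) peaks later, while the PCC NBR and the contralateral PBR stay
comparatively stable. Because a conventional first-level GLM convolves
event timings with a fixed canonical double-gamma kernel, a response that
peaks at 18 s rather than 5 s is scored as weak even when its true
amplitude is unchanged: apparent ageing effects conflate amplitude change
with kernel misfit. This package implements the full analysis chain
needed to study — and disentangle — these two effects, together with a
synthetic-data generator so every stage is testable without any scanner
data.

## Forward model

The evoked response in region $r$ of a subject of age $a$ is modelled as

$$ y(t) \;=\; \beta_0 \;+\; A_r(a)\, \big(s * h_{r,a}\big)(t) \;+\;
   d(t) \;+\; \varepsilon(t), $$

where $s$ is the neural-input train (one constant-amplitude 50 ms boxcar
per trial), $h_{r,a}$ is a unit-extremum latency-stretched double-gamma
kernel, $A_r(a)$ the signed response amplitude in fractional signal
change, $d$ a polynomial drift and $\varepsilon$ AR(1) noise. The
convolution is evaluated on a 0.01 s grid and sampled at volume times
$t_v = v \cdot \mathrm{TR}$. Regressors are scaled so that an isolated
event produces unit extremum deviation, which makes the fitted
beta-weight directly interpretable as per-event peak signal change.

A note on the fine grid: 0.01 s is used (rather than the 50 ms event
duration) because it divides the TR of 1.97 s (197 steps), the 2 s event
grid (200 steps) and the event duration (5 steps) exactly, so volume
times and event onsets both fall on grid points and no interpolation
error enters the matched-kernel algebra.

## The task design

The paradigm generator emulates a rapid event-related audiovisual
sensorimotor task: 120 bimodal trials (three tone frequencies in equal
numbers) and 8 unimodal catch trials on a 2 s placement grid with
pseudo-random null gaps, constrained so observed stimulus onset
asynchronies span 2–26 s, over 261 volumes at TR 1.97 s. A literal binary
m-sequence scheduler is deliberately not implemented: the published
construction is under-determined (a binary m-sequence of length 255 does
not by itself produce 26 s gaps), so a grid-based pseudo-random scheduler
constrained to the same SOA range is used, with the m-sequence option
noted as future work. Gap lengths follow a geometric-flavoured
distribution (ratio 0.55), giving the short-SOA-dominated mix of rapid
designs and a mean SOA near 4 s for the study's trial counts. Practice
and error trials are not generated; at the task's ~99% accuracy their
effect at desk scale is negligible.

## Lifespan trajectories

Region HR parameters follow linear trajectories in age anchored at the
mean ages of the youngest and oldest age bins (25.8 and 82.6 years):

```{r}
default_trajectories()
```

The iSM1 amplitude shallows from −0.034 to −0.013 while its time-to-peak
lengthens from 10 s to 18 s; cSM1 and thalamus latencies lengthen
modestly; amplitudes of the PBR regions and of the PCC NBR are constant.
Interpolation is pure linear (extrapolated beyond the anchors, without
clamping, so the age–amplitude relation has no flat segments that would
bias slope-recovery checks); over the supported range of 18–88 years all
amplitudes keep their sign, preserving the PBR/NBR polarity invariants.

PBR amplitudes and the V1/PCC latencies are not constrained by published
decile values; the defaults (cSM1 +0.08, V1 +0.10, thalamus +0.04, PCC
−0.03 fractional signal change; V1 time-to-peak 8.8 s, PCC 11 s) are
plausible field values chosen once — PBRs a few times larger than NBRs,
visual cortex strongest, subcortex weakest and earliest-peaking.

## Noise, drift, between-subject variability, motion

* **Noise**: AR(1) with marginal SD 0.01 of baseline (temporal SNR ≈ 100,
  typical of 3 T cortical grey matter) and lag-1 correlation 0.3.
* **Drift**: polynomial on time scaled to [−1, 1], default coefficients
  (0.005, −0.003) — sub-percent slow drift.
* **Between-subject variability** (`simulate_cohort`): multiplicative
  amplitude jitter with 10% relative SD (sign-preserving) and additive
  time-to-peak jitter with SD 1.5 s truncated to [4, 22] s. The 10%
  amplitude SD encodes the design condition that age dominates amplitude
  variance in a default cohort (age–amplitude correlation above 0.9);
  observed single-subject scatter in real data is larger, but much of it
  is measurement noise, which the generator contributes separately
  through the AR(1) term at estimation time.
* **Motion**: a smoothed six-parameter random walk rescaled so the
  subject's total framewise displacement follows the line through the
  observed decile means (≈ 18.7 + 1.37 × age, in mm) with lognormal
  scatter (SD 0.25 on the log scale), reproducing the rise of head motion
  with age.

Seeds are mandatory fields of the subject specification, never ambient
state; identical seeds give byte-identical data.

## First-level GLM

Each of the five conditions gets one regressor; the six demeaned motion
parameters, an intercept and a second-order polynomial drift are
nuisance. The contrast of interest is the mean over the five condition
regressors, with both signs evaluated (PBR and NBR). Fitting is ordinary
least squares per voxel; t statistics are mapped to Z through the t CDF
and normal quantile in log-probability space (monotone, odd, and stable
for |t| in the hundreds). Voxels with numerically zero residual variance
are flagged invalid rather than assigned infinite Z. Prewhitening and
mixed-effects variance modelling are intentionally out of scope: the
inference engine is not what is under study here, and the simulated AR(1)
noise mildly inflates nominal significance equally under every kernel
being compared.

No high-pass filter is applied; slow confounds are handled by the
polynomial drift regressors (order 2 by default), which is also what the
deconvolution uses, keeping nuisance handling consistent across stages.

Spatial smoothing is a separable Gaussian, specified as FWHM in mm and
converted per axis by the voxel dimensions, with reflective boundaries
(which conserve the per-volume total signal); `fwhm = 0` is the identity.

## FIR deconvolution

The HR of a region is estimated without shape assumptions: all events are
pooled into one constant-amplitude train binned at the volume grid
(mirroring the original analysis, which used button-press timings as a
constant-amplitude delta function), and one unknown per lag bin
0..⌊window/TR⌋ is estimated by least squares alongside the drift
nuisance. The default window is 24 s: latencies up to 18 s plus an
undershoot must fit inside it, and at TR 1.97 s it yields 13 lag bins —
comfortably estimable from ~128 events in 261 volumes. The estimator is
unregularized by default; a ridge option exists for pathological
schedules, and rank-deficient lag designs raise an error naming the
offending lags.

Two accuracy regimes matter and are checked separately:

1. **Identity**: the FIR estimator exactly inverts its own forward
   operator (`fir_convolve`); on noiseless data built with that operator
   the recovered HR matches to machine precision.
2. **Continuous-time recovery**: data generated by the fine-grid forward
   model have event onsets that do not align with volume times (2 s grid
   against 1.97 s TR), so TR-binned FIR recovery carries an intrinsic
   discretization floor. At generator-default noise, 20-subject runs show
   mean absolute time-to-peak error around 1–1.4 s (within one TR bin)
   and mean relative peak-magnitude error around 7–11%.

**Peak metrics**: the peak magnitude is the signed sample of maximal
absolute value and the time-to-peak its bin time, with ties broken by the
earliest bin — a deterministic rule that matters only for degenerate
discrete responses.

**Normalization**: decile-mean HRs are normalized by the maximum
*absolute* amplitude with sign preserved, so an NBR kernel has extremum
−1. Dividing a negative-going HR by its signed maximum would invert and
mis-scale it. The consequence is a polarity bookkeeping rule: with a
negative-going kernel, the *positive* contrast of the refitted GLM
carries the NBR magnitude; results record the kernel polarity so callers
orient contrasts correctly.

## Re-analysis with data-driven kernels

`lifespan_kernel_comparison` runs the full loop: synthesize each
subject's region timecourse, deconvolve its HR, average HRs within
deciles, normalize, and refit every subject twice — once with the
canonical kernel, once with the subject's decile-mean kernel, all other
GLM parameters identical. The per-decile mean |Z| profiles, expressed as
percent of the youngest decile, quantify how much of the apparent decline
the canonical kernel manufactures. Because estimating a decile kernel
from the same subjects it is then applied to is mildly circular, a
split-half option estimates kernels on one half of each decile and
applies them to the other half.

Cohort-level computations operate on region-mean timecourses rather than
full volumes: for a generator whose voxels within a region share one
signal, the region mean is a sufficient statistic and the result is
statistically identical to voxelwise fitting followed by ROI averaging,
at a small fraction of the cost. Volumetric fitting, ROI extraction and
second-level maps are exercised on smaller grids.

## ROI and extent conventions

* The subject-specific ROI is a 3×3×3 cube (27 voxels) centred on the
  peak-response voxel inside the anatomical mask; cubes are clipped at
  volume boundaries rather than shifted (a corner peak keeps 8 voxels),
  and only the peak — not the whole cube — must lie inside the mask.
  Peak ties resolve to the lowest linear index. Peak coordinates are
  reported as 0-based voxel indices on the toy atlas, not MNI mm.
* Spatial extent thresholds betas at 5% of the subject's maximum,
  *separately per sign* (max positive beta for PBR, max |negative beta|
  for NBR), since the positive and negative responses are thresholded
  separately; a global-magnitude option is provided. Proportions are
  taken over the sensorimotor mask and their PBR/NBR ratio is flagged
  undefined when no negative voxels survive.
* Tertile splits rank by value and give each group ⌊n/3⌋ subjects with
  the remainder assigned to the middle group first, then the lower group
  — the rule forced by the published 18/19/18 split of 55 subjects.
* Framewise displacement is the sum of absolute volume-to-volume
  differences of the six parameters, rotations converted to mm on a
  50 mm sphere (radius configurable); totals are sums over volumes.

## Group statistics

Second-level models regress subject maps on an intercept plus a
mean-subtracted covariate (the intercept map is then exactly the group
mean). Decile pairs are compared with pooled-variance two-sample t maps;
post-hoc tests are Welch t (the variance-equality assumption is not worth
defending for age-binned humans); correlations are Pearson with the t
transform; "age-corrected" values are residuals of a linear fit on age
(residualize-then-correlate equals the partial correlation given age, an
identity the tests verify numerically); and the incremental-variance
question — does an NBR statistic explain behaviour beyond age? — is a
partial F test between nested OLS fits. p values are always reported
uncorrected with a Bonferroni column alongside; nothing corrects
silently. Map summaries use a voxelwise |Z| > 3.1 threshold in place of
cluster-level correction, which is out of scope.

All of these wrap base R engines (`oneway.test`, `t.test`, `cor.test`,
`lm`/`anova`) behind a stable interface; the test suite cross-checks
each against explicit sum-of-squares or formula oracles.

## What the generator does and does not emulate

Emulated: event timing statistics of the rapid design; region-specific
HR amplitude and latency trajectories with age; AR(1)-plus-drift noise;
age-increasing head motion; reproducibility from explicit seeds.

Not emulated: k-space physics, susceptibility distortion, slice-timing
offsets, spatially correlated physiological noise, vascular
heterogeneity within regions, partial-volume boundaries, and
between-region noise correlations. Consequently, passing tests show that
the *analysis machinery* is correct and that the kernel-misfit mechanism
behaves as theorized under known ground truth; they do not certify
performance on real scanner data, where noise structure and HR shape
variation are richer.

## Problem sizes and numerical choices

Cohort checks use 5–10 subjects per decile and the full 261-volume run;
the slope-recovery check uses 200 replicate cohorts of 5 subjects per
decile; volumetric tests use 12×12×6 to 24×24×12 grids. These sizes give
stable statistics at interactive runtimes. Other numerical choices:
OLS via QR with an explicit rank check; degenerate voxels masked, never
given sentinel Z values; FFT convolution zero-padded to a power of two;
reflective smoothing boundaries; double-gamma defaults (shapes 6 and 16,
unit dispersions, undershoot ratio 1/6) exposed as arguments.

## Known limitations

* OLS with AR(1) noise mildly miscalibrates absolute Z values; all
  kernel comparisons are within-subject and unaffected in direction.
* TR-binned FIR metrics inherit a ±1-bin latency quantization.
* The toy atlas has no anatomical realism; extent statistics on it test
  bookkeeping, not neuroanatomy.
* The decile-kernel re-analysis is circular unless the split-half option
  is used; both modes are provided.
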
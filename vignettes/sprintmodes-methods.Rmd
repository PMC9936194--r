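---
title: "Identifying whole-body modes of sprint performance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying whole-body modes of sprint performance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sprintmodes)
```

## The problem

Peak over-ground sprint velocity emerges from the coordination of the
whole body, not from any single joint in isolation. Rather than
pre-selecting discrete parameters (a joint angle at toe-off, a single
muscle's onset time), `sprintmodes` treats each athlete's stride as a
whole waveform: the time-normalized trajectories of a 64-marker
point cloud, and the time-normalized linear envelopes of nine surface-EMG
channels. Waveform principal component analysis (PCA) then extracts the
cohort's dominant *modes of variation* — each principal component is
itself a full-body movement (or muscle-activation) pattern — and
stepwise regression asks which modes, together with sex, age and
height, are associated with each athlete's peak sprint velocity.
Finally, single- and multi-component reconstruction (SCR/MCR) turns the
selected modes back into interpretable "fast" versus "slow" waveforms
by evaluating the PCA model at the 95th and 5th percentile scores.

The pipeline has two arms that share one structure:

1. **Kinematic arm.** A 60 Hz, 64-marker point cloud (read from C3D) is
   registered (origin reset at the right ankle's start position; PCA of
   the pooled marker-frame positions realigns the global frame so x is
   the axis of progression; crop at 60 m of T8 travel), the speed
   profile of the T8 marker locates peak velocity, strides are
   segmented at right-ankle height minima, the five strides about the
   peak are each time-normalized to 101 points, de-biased by
   subtracting T12, height-scaled, ensemble-averaged and flattened to a
   `64 * 3 * 101 = 19392`-element feature vector.
2. **EMG arm.** Nine channels at 2000 Hz are full-wave rectified,
   low-pass filtered (dual-pass 2nd-order Butterworth, 250 Hz default),
   amplitude-normalized to the mean of the three highest peaks within
   the first 20 m of the sprint, segmented with the same five stride
   windows (mapped by the 2000/60 rate ratio), time-normalized to 2000
   points per cycle, ensemble-averaged and flattened to a
   `9 * 2000 = 18000`-element vector.

Per arm, the subjects-by-features matrix is centred (not scaled — all
features within a matrix share units, and scaling would distort the
waveform geometry), decomposed by SVD, and the leading components
covering more than 95% of the variance are retained as regression
candidates alongside sex, age and height.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| crop distance | 60 | m | the sprint distance analysed |
| normalized kinematic points | 101 | – | one stride, 0–100% in 1% steps |
| normalized EMG points | 2000 | – | one stride at EMG resolution |
| envelope cutoff | 250 | Hz | configurable; `residualAnalysis()` re-derives it from the data (Winter's construction) |
| EMG normalization window | 20 | m | dynamic peak reference from the acceleration phase |
| variance retention | 0.95 | – | smallest PC prefix explaining >95% |
| stepwise entry / exit | 0.05 / 0.10 | p | exit tolerance 0.10; 0.05 entry is the conventional pairing and, with entry ≤ exit, provably cannot cycle |
| reconstruction percentiles | 0.05 / 0.95 | – | empirical score quantiles (linear interpolation) |

All of these are exposed as arguments and collected in the single
configuration consumed by `runPipeline()`.

## Design choices where the design was open

* **Speed definition.** The trunk speed that locates the peak defaults
  to the norm of the T8 position derivative (`mode = "vector"`), which
  is origin- and direction-independent. The literal
  derivative-of-the-norm reading (`mode = "norm-derivative"`) is
  available; after registration the two nearly coincide for forward
  sprinting, and they agree exactly when T8 moves through the origin
  along +x.
* **Registration axes.** The leading component of the pooled point
  cloud is always the progression axis (sign: net T8 displacement). Of
  the two remaining components, the one better aligned with the
  original vertical becomes z and the other y, with y negated if needed
  for a right-handed frame. Anchoring the vertical by alignment rather
  than by variance rank matters because a standing-height point cloud's
  vertical spread can rival its mediolateral spread; when the
  mediolateral component genuinely ranks second the rule reduces to
  "y = PC2, z = PC3". Rotation is computed on positions after origin
  reset; no separate drift model is fitted — the origin reset plus
  rotation is the whole correction.
* **Stride detector.** Right-ankle z is smoothed with a dual-pass
  2nd-order low-pass at 4 Hz before trough finding; the minimum trough
  separation is 0.3 times the dominant period estimated from the
  signal's autocorrelation; ties break to the earliest frame. A
  "stride" is minimum-to-minimum of the right ankle (one full gait
  cycle of the right side).
* **Cycle selection.** "About peak velocity" is read symmetrically: the
  stride containing the peak frame is window 3 of 5, and the block
  shifts inward at the ends of the trial. With exactly six events there
  is no choice to make.
* **Spline degree.** Cubic splines for time normalization (the degree
  is otherwise unspecified in common practice); on a 60 Hz stride a
  cubic resampling of a sinusoid is accurate to better than 1e-3.
* **Stepwise numerics.** Partial-F p-values drive both entry and
  removal; covariates compete as ordinary candidates; the final model
  is refitted by OLS, so the reported table always equals a direct
  refit. Forward entry stops once the fit is numerically exact
  (relative SSE below 1e-20) — p-values computed on eps-scale residuals
  are meaningless and would otherwise admit spurious terms.
* **Zero-phase filtering.** Forward–backward filtering uses
  odd-reflection padding with steady-state initial conditions, so a
  constant signal passes through at machine precision and a symmetric
  burst keeps its peak position. The dual pass squares the magnitude
  response: the attenuation at the design cutoff is
  (1/sqrt(2))^2 ≈ 0.501. No cutoff-warping correction is applied,
  matching the stated filter contract.
* **Residual analysis.** For each candidate cutoff the RMS difference
  between filtered and rectified signal is computed; a line through the
  high-frequency (noise-dominated) tail is extrapolated to zero
  frequency and the chosen cutoff is where the residual curve meets
  that intercept. Residuals below 0.1% of the signal RMS are treated as
  a noiseless floor, in which case the lowest candidate is returned.
* **Reconstruction percentiles** are empirical per-component score
  quantiles across subjects — the established convention for
  single-component reconstruction. `mcr(..., alignToOutcome = TRUE)`
  flips components with negative regression coefficients so that the
  "upper" reconstruction is the one that maximizes predicted velocity;
  the literal unaligned sums are the default.
* **EMG cycle count.** The five EMG cycles are ensemble-averaged
  exactly like the kinematic cycles (the 18000-element layout implies a
  single averaged cycle per subject). Where printed index ranges and
  stated point counts conflict in common descriptions of this layout,
  the 2000-points-per-cycle reading wins.

## What the synthetic cohort emulates

Because real instrumented-sprint cohorts are rarely public, the
generator in `cohortSpec()`/`generateCohort()` is a first-class module
and the package's primary test surface. Its defaults describe the study
conditions the package targets:

* 40 subjects, each sprinting past 62 m with an exponential
  acceleration profile (time constant 1.7 s) to a subject-specific peak
  speed near 8 m/s; stride rate 2 Hz; 60 Hz markers, 2000 Hz EMG.
* A body-layout point cloud: each marker is an anatomy-based offset
  plus first- and second-harmonic sinusoids of the stride phase; the
  right-ankle vertical trajectory has one sharp minimum per stride.
  A per-subject multiplicative amplitude jitter (sd 2%) provides
  realistic nuisance variance so that the >95% retention rule has
  something to do.
* Three injected kinematic modes of variation: unit-norm feature-space
  waveforms with disjoint marker support (never touching T8, T12 or the
  right ankle, so speed, de-bias and segmentation are untouched),
  folded back into the trajectories as height-scaled periodic
  perturbations. Mode scores are Gaussian with sds 0.25, 0.18, 0.12.
* A known linear velocity model: intercept 7.7 m/s (female baseline),
  mode weights +1.6, −1.2, +2.0 m/s per unit score, a +0.5 m/s sex
  effect (sex coded 0 = female, 1 = male, so a positive coefficient
  means faster males), and Gaussian noise with sd 0.05 m/s. Under the
  default score sds and a ~2:1 male:female mix this gives cohort means
  near 7.9 ± 0.6 m/s, the realistic range for university-age sprinters.
* Recording imperfections: linear lateral drift (0.05 m/s) identical
  across markers, and a 15° yaw-misaligned global frame — exactly the
  defects the registration stage exists to undo.
* EMG: per-muscle Gaussian burst envelopes at muscle-specific stride
  phases plus zero-mean carrier noise; odd EMG modes shift the burst
  timing of the posterior-chain channels (BF, GMAX, LES, LD), even
  modes scale the amplitude of the anterior channels (EO, VLO, RF,
  GAS). EMG modes carry known scores but are not velocity-linked by
  default: the velocity model is attached to the kinematic modes, which
  keeps the ground truth of the recovery experiment single-sourced.

**What it does not emulate:** soft-tissue artifact, ferromagnetic
interference, nonstationary stride rate during the acceleration phase,
inter-muscle crosstalk, and ground-reaction forces. Passing tests on
this cohort therefore demonstrate that the pipeline recovers structure
it is designed to recover under controlled imperfections — not that any
particular real cohort satisfies these assumptions.

One deliberate realism consequence: the measured peak speed of the T8
marker exceeds the body's true forward speed by the stride-harmonic
oscillation of the trunk, whose amplitude scales with stature. The
stepwise model may therefore legitimately pick up `height` alongside
the injected modes; recovery is judged by whether the true modes and
sex are selected, with extra covariate terms permitted.

## The recovery experiment

`modeRecoveryExperiment()` repeats, per seed: simulate a cohort, run
the complete kinematic arm, fit the PCA, retain to 95%, run stepwise,
and compare with truth. Two details matter:

* **Mode matching.** Injected modes are matched to retained components
  by the largest absolute inner product between loading and mode
  waveform.
* **Coefficients are compared in feature space.** With finite samples
  the mode scores are slightly correlated, so PCA returns a rotation of
  the injected modes; comparing per-PC coefficients to per-mode weights
  would confound that rotation with estimation error. Instead the
  fitted model's feature-space gradient (the sum of selected loadings
  weighted by their estimates) is projected onto each true mode
  waveform, which is invariant to the basis rotation. Signs are aligned
  before comparison because a loading and its negation describe the
  same mode.

Under the default conditions (40 subjects, 3 modes, noise sd 0.05 m/s,
sex effect 0.5 m/s) the true modes and sex are recovered in well over
90% of seeded replicates with coefficient errors of a few percent. The
test suite runs 50 replicates; the acceptance script reports 25. These
sizes keep a full run in minutes while leaving the success-rate
estimate with a standard error of a few percent.

## Numerical and degenerate-input policy

* PCA requires at least two subjects and non-constant features;
  loadings get a deterministic sign (largest-magnitude element
  positive) so repeated fits are bit-identical.
* The stride detector refuses trials with fewer than six minima;
  the generator raises a dedicated condition
  (`sprintmodesShortTrial`) when a spec cannot contain five strides.
* C3D dropout gaps up to 0.25 s are linearly interpolated; longer gaps
  are an error rather than silently smoothed.
* Stepwise validates `pEnter <= pRemove` (the no-cycling condition) and
  returns an intercept-only model when nothing enters.
* Exactly tied stride-trough frames (a trough precisely between two
  samples) are resolved to the earlier frame; the tie is genuinely
  ambiguous at the sampling resolution.

## Known limitations

* The 64-marker label manifest is a package convention (vendor exports
  vary); `readMarkerTrial(labelMap =)` adapts other naming schemes.
* The C3D layer covers Intel-order files with 3D point data (integer or
  float); analog channels stored in C3D are skipped rather than parsed.
* Kinematic-to-EMG synchronization assumes simultaneous starts and
  exact nominal rates.
* The stepwise procedure inherits the usual caveats of stepwise
  selection (post-selection inference is optimistic); the package
  reports the conventional OLS table for the final model without
  selection-adjusted p-values.
* MCR sums percentile-scaled loadings; with many components the bounds
  can drift outside the convex hull of observed subjects — they are
  interpretive envelopes, not predicted athletes.
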
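# sprintmodes

Data-driven identification of the whole-body kinematic and
neuromuscular features associated with peak over-ground sprint
velocity.

Sprinting is a whole-body skill: peak velocity depends on the timing of
the contralateral arm and leg swing, trunk dynamics and the sequencing
of muscle activation, not on any single joint parameter. `sprintmodes`
implements a waveform-PCA framework for wearable-sensor sprint trials:

1. **Registration.** Each 60 Hz, 64-marker point-cloud trial (C3D) is
   re-expressed in a common frame: the origin is reset to the right
   ankle's starting position; PCA of the pooled marker-frame positions
   yields the axes of progression (x), mediolateral motion (y) and
   vertical motion (z), undoing sensor drift and calibration yaw; the
   trial is cropped at 60 m of T8 travel.
2. **Stride cycles.** The T8 speed profile locates peak velocity;
   strides are segmented at right-ankle height minima; the five strides
   about the peak are time-normalized to 101 points, de-biased by
   subtracting T12, height-scaled, ensemble-averaged and flattened to a
   1 × 19392 feature vector (64 markers × 3 axes × 101 points).
3. **EMG envelopes.** Nine channels at 2000 Hz are rectified, low-pass
   filtered (zero-phase dual-pass 2nd-order Butterworth, 250 Hz
   default, with a residual-analysis tool to re-derive the cutoff),
   normalized to the mean of the three highest peaks in the first 20 m,
   cycled with the same stride windows and flattened to 1 × 18000
   (9 channels × 2000 points).
4. **Waveform PCA.** Per arm, the subjects × features matrix *X* is
   column-centred and decomposed, `X = x̄ + Σ zₖ uₖ`; components
   explaining >95% cumulative variance are retained.
5. **Stepwise regression.** Retained PC scores plus sex, age and height
   compete as predictors of peak velocity (partial-F entry p < 0.05,
   exit p > 0.10, OLS refit).
6. **Reconstruction.** Selected modes are visualized as bounds
   `x̂_U = x̄ + Σ uₙ z₉₅,ₙ` and `x̂_L = x̄ + Σ uₙ z₀₅,ₙ` (single- or
   multi-component; optionally sign-aligned so the upper bound is the
   "fast" pattern), exportable as 101-frame C3D avatars and per-muscle
   CSV waveforms.

Because instrumented sprint cohorts are rarely shareable, the package
includes a synthetic-cohort generator with known ground truth — modes
of variation injected in feature space and folded back into marker
trajectories, a known linear velocity model, sensor drift and frame
misalignment — which is also how the package validates itself end to
end.

## Worked example

Simulate a 40-subject cohort whose peak velocity follows a known linear
model (weights +1.6, −1.2, +2.0 m/s per unit score on three injected
movement modes, +0.5 m/s for male subjects, 0.05 m/s noise), run the
complete kinematic arm, and compare with the truth:

```r
library(sprintmodes)

spec <- cohortSpec(seed = 42)   # 40 subjects, default study conditions
out  <- recoverCohort(spec)     # simulate -> register -> cycles -> PCA -> stepwise
out$model
#> StepwiseModel: 4 selected terms
#>          term estimate      se      t         p
#> 1 (Intercept)   8.0155 0.01596 502.36 4.087e-69
#> 2         PC2   2.1362 0.05155  41.44 2.449e-31
#> 3         sex   0.4942 0.01886  26.21 1.360e-24
#> 4         PC1  -0.9678 0.03835 -25.23 4.816e-24
#> 5         PC3  -1.4415 0.06909 -20.86 2.497e-21

out$matchedPcs              # which retained PC carries each injected mode
#> [1] 1 2 3
round(out$coefEstimates, 3) # feature-space mode coefficients (truth: 1.6, -1.2, 2.0)
#> [1]  1.526 -1.294  1.884
```

All three injected modes and the sex effect are selected; the
regression table is in PC coordinates (a rotation of the injected
modes, since finite-sample mode scores are slightly correlated), while
`coefEstimates` projects the fitted model back onto the true mode
waveforms and recovers the generating weights to within a few percent.
The sex coefficient (0.494) matches the simulated 0.5 m/s effect.

For file-based data the same stages run from a single configuration:

```r
runPipeline(list(
  subjects = list(
    list(id = "S01", marker = "S01.c3d", emg = "S01_emg.csv",
         height = 1.78, sex = 1, age = 22)
    # ...
  )
), outDir = "results/")
```

which writes score/loading summaries, Table-style regression reports,
fast/slow C3D avatars and EMG waveform CSVs, a run log, and a manifest
with file checksums (reruns are bit-identical).

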
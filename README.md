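# luqspect

Dead-time calibration and activity quantification for ¹⁷⁷Lu quantitative
SPECT (QSPECT).

## The problem

Quantitative ¹⁷⁷Lu SPECT — the basis of dosimetry in radionuclide therapies
such as PRRT — converts reconstructed counts to absolute activity through a
camera **calibration factor** *CF* (cps/MBq). At therapeutic activities the
camera loses counts to **dead time** (DT), so the observed primary
(scatter-corrected photopeak) count rate *R*<sub>Po</sub> underestimates the
true rate *R*<sub>Pt</sub>, and with it the activity — by up to ~23% when
the correction factor reaches 1.30. Modern gamma cameras follow the
**paralysable** model

&nbsp;&nbsp;&nbsp;&nbsp;*R*<sub>o</sub> = *R*<sub>t</sub> · e^(−*R*<sub>t</sub>·τ),

whose observed rate peaks at 1/(e·τ) — about 669 kcps for τ = 0.550 μs.
Because photons of *any* energy generate dead time, and the spectrum shape
depends strongly on the scanned geometry, the loss of primary counts is best
predicted from the **wide-spectrum** observed rate *R*<sub>Wo</sub> (summed
over contiguous energy windows covering e.g. 18–680 keV) rather than from
the photopeak rate. `luqspect` implements this wide-spectrum-driven
calibration:

&nbsp;&nbsp;&nbsp;&nbsp;*R*<sub>Wo</sub> = *CF* · *X*<sub>W</sub> · e^(−*CF*·*X*<sub>W</sub>·τ),
&nbsp;&nbsp;&nbsp;&nbsp;*X*<sub>W</sub> = *A* · *R*<sub>Wo</sub>/*R*<sub>Po</sub>,

fitted over a serial acquisition series of known activities *A*, either
jointly in *CF* and τ (**Method B**) or in two steps — *CF* from a
through-origin fit of dead-time-free low-rate samples, then τ with *CF*
fixed (**Method A**). The fitted τ then yields the per-acquisition
correction factor *f* = *R*<sub>Pt</sub>/*R*<sub>Po</sub> solving
1 = *f*·e^(−*f*·*R*<sub>Wo</sub>·τ) (a Lambert-W inversion), and recovered
activity *A*<sub>rec</sub> = *R*<sub>Po</sub>·*f*/*CF*.

The package provides:

- **Energy-window bookkeeping** — the six-window ¹⁷⁷Lu scheme (20%
  photopeak at 208 keV, adjacent scatter windows, general-scatter windows
  to 680 keV), the photopeak/3W/4W/6W combinations, and TEW/DEW scatter
  correction.
- **Paralysable-model toolbox** — forward losses, analytic maximum,
  Lambert-W inversion with bisection safeguard, correction factors.
- **Calibration** — Methods A and B, Poisson-weighted variants, detection
  of the usable operating range of the system (sensitivity drop and
  per-detector divergence beyond saturation), sensitivity tables.
- **Segmentation** — whole-volume, threshold (1%-of-max) and circular-ROI
  primary rates from reconstructed count volumes (NIfTI I/O).
- **Quantification** — dead-time-corrected activity recovery, accuracy
  scoring, and the rescale slope mapping voxel counts to Bq/mL.
- **Simulator** — a synthetic dual-head camera and phantom family
  (sources in air, CTDI cylinders, Jaszczak) with known ground truth,
  geometry-dependent spectral ratios, Poisson noise, ¹⁷⁷Lu decay, pile-up
  displacement and post-saturation detector divergence, for validation and
  recovery studies.

## Worked example

Calibrate a simulated camera from a serial planar series (17 activities,
19 MBq–15.1 GBq, 60-s frames, Poisson counting noise) and quantify the same
series with the fitted parameters:

```r
library(luqspect)

camera  <- camera_truth()                 # truth: CF = 9.36 cps/MBq, tau = 0.550 us
phantom <- phantom_truth("Air-2D")
records <- generate_series(camera, phantom, default_planar_plan(seed = 3))

fit <- calibrate(records, method = "B", combination = "6W", scatter = "TEW")
fit
#> <calibration_fit>  Method B, driver 6W
#>   CF  = 9.37 +/- 0.0026 cps/MBq
#>   tau = 0.5538 +/- 0.0008 us
#>   samples used: 16 (1 excluded)
#>   usable range: A <= 9962 MBq, photopeak <= 79.95 kcps, wide <= 296.2 kcps

q <- quantify_samples(build_samples(records), fit)
s <- accuracy_summary(q)
sprintf("accuracy: %.2f +/- %.2f %% over %d in-range acquisitions",
        s$mean, s$sd, s$n)
#> [1] "accuracy: -0.04 +/- 0.21 % over 16 in-range acquisitions"

correction_factor(2e5, fit$tau)           # DT correction at 200 kcps wide rate
#> [1] 1.133797
```

Reading the output: the joint fit recovers the true calibration factor
(9.37 ± 0.0026 vs 9.36 cps/MBq) and dead-time constant (0.554 ± 0.001 vs
0.550 μs); the topmost acquisition, beyond the camera's saturation, is
detected and excluded, and the usable operating range is reported as the
last reliable sample's activity and count rates. Dead-time-corrected
quantification of the series is accurate to a fraction of a percent, and at
an observed wide-spectrum rate of 200 kcps primary counts must be scaled up
by ~13%.

The same workflow runs from a shell via the thin wrappers in `inst/cli/`
(`simulate.R`, `calibrate.R`, `quantify.R`), and on real data from an
acquisition CSV (see `?read_acquisitions` for the column contract).

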
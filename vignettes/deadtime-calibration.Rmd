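---
title: "Wide-spectrum dead-time calibration for Lu-177 quantitative SPECT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wide-spectrum dead-time calibration for Lu-177 quantitative SPECT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(luqspect)
```

## The model

A paralysable detector that receives a true event rate $R_t$ registers an
observed rate

$$R_o = R_t\,e^{-R_t\tau},$$

where $\tau$ is the dead-time constant. The observed rate is unimodal in
$R_t$, with maximum $1/(e\tau)$ at $R_t = 1/\tau$; no observed rate above
that ceiling is possible, and every observed rate below it corresponds to
two true rates. All inversions in this package return the physical,
below-saturation branch ($R_t\tau < 1$).

For quantitative SPECT the rate of interest is the *primary* rate
$R_{Po}$ — scatter-corrected photopeak counts per second — but the dead
time is generated by photons of *every* energy the crystal records. The
spectrum shape depends on the scanned object (more scattering medium means
relatively fewer photopeak counts), so a photopeak-driven loss model is
geometry-dependent while a wide-spectrum-driven one is not. The package
therefore models the losses of primary counts as driven by the observed
wide-spectrum rate $R_{Wo}$:

$$R_{Wo} = CF \cdot X_W\, e^{-CF\, X_W\, \tau},
  \qquad X_W = A\,\frac{R_{Wo}}{R_{Po}},$$

with $A$ the known activity and $CF = R_{Pt}/A$ the dead-time-free
calibration factor. Two estimation procedures are provided:

* **Method A** (two-step): $CF$ from an origin-forced ordinary
  least-squares fit of $R_{Po}$ on $A$ over the *dead-time-free* subset
  (samples whose correction factor is within `dt_threshold` of 1, default
  1%), then $\tau$ from a nonlinear fit of the model above with $CF$
  fixed.
* **Method B** (joint): one nonlinear fit resolving $CF$ and $\tau$
  simultaneously over the full usable range. The functional form passes
  through the origin by construction, so no dead-time-free subset needs to
  be designated.

Once $\tau$ is known, the correction factor applying to an observed
primary rate is the solution $f$ of $1 = f\,e^{-f R_{Wo}\tau}$,
equivalently $f = R_{Wt}/R_{Wo}$ evaluated by inverting the paralysable
model at $R_{Wo}$; recovered activity is $A_\mathrm{rec} = R_{Po} f / CF$.
Note that $\tau$ here predicts the losses of *primary* counts from the
wide-spectrum rate; it is not an estimate of the dead time affecting
$R_{Wo}$ itself. Pulse pile-up displaces surviving primary events out of
the photopeak, which makes the primary-loss $\tau$ larger than a
$\tau$ fitted to the wide-spectrum rate's own losses — the simulator's
pile-up mode reproduces exactly this ordering.

## Energy windows and scatter correction

The bundled scheme (`lu177_scheme()`) has a 20% photopeak window at
208 keV, two adjacent scatter windows each half the photopeak width, and
three general-scatter windows extending coverage to 18–680 keV, combined
as `photopeak`, `3W`, `4W` and `6W`. Because the vendor-reported integer
limits do not all match exact centre±width arithmetic (e.g. 111 keV ± 50%
gives 55.5–166.5 but is reported 55–166, and the rounding convention is
not documented), the bundled scheme stores the reported integer limits
verbatim; `window_limits()` computes exact real limits and rounds half-up
only for display.

TEW scatter correction subtracts the lower and upper scatter-window counts
from photopeak counts; DEW subtracts only the lower. Both are plain count
subtractions: since each scatter window is half the photopeak width, the
standard trapezoidal scatter estimate reduces algebraically to the plain
sum (a width-weighted variant is available behind `width_weighted = TRUE`
and is identical for the bundled scheme). No scaling is applied to the
DEW subtraction. Negative net counts on noisy low-count frames are clipped
to zero with a warning by default; a `"keep"` policy preserves them for
fitting studies where clipping would bias low-rate averages.

## Numerical choices

* **Inversion.** The below-saturation inverse uses the principal branch of
  the Lambert W function, $R_t = -W_0(-R_o\tau)/\tau$, computed by a
  vectorized Halley iteration with a hard 100-iteration cap, a series-based
  starting point near the branch point, and a residual check; any element
  failing the check falls back to bisection on $[R_o, 1/\tau]$ (absolute
  tolerance $10^{-12}$ on $R_t\tau$). Inversion is refused within a
  $10^{-9}$ relative margin of the apex $1/(e\tau)$, where the two branches
  meet and the inverse is ill-conditioned.
* **Fits.** Nonlinear fits use Levenberg–Marquardt (`minpack.lm`), with
  $\tau$ parameterized as $\log\tau$ for positivity and conditioning (its
  standard error is mapped back by the delta method). Starting values:
  $CF$ from a through-origin slope of the lowest-decile $X_W$ points,
  $\tau_0 = 0.5\ \mu s$. If a fit contaminated by post-saturation samples
  fails, a derivative-free Nelder–Mead restart supplies new starting
  values. Fits are unweighted by default — the estimators are then plain
  least squares on rates — with optional Poisson-variance weighting
  (`weights = "poisson"`, inverse-rate). Where estimates are *compared
  through their standard errors* (the geometry-independence check below)
  the weighted variant is used, because unweighted-LS standard errors are
  anti-conservative under Poisson counting noise.
* **Dead-time-free selection.** `select_dt_free()` keeps samples with
  $f - 1 <$ `dt_threshold` under a provisional $\tau$. The provisional
  $\tau$ comes from a Method B fit (one iteration resolves the
  circularity of needing $\tau$ to find the dead-time-free subset); a
  fixed activity cutoff can be supplied instead. Note a structural
  consequence: the origin-forced OLS weights samples by $A^2$, so the
  subset's highest-rate sample dominates and Method A's $CF$ carries a
  deterministic downward bias of roughly half the threshold (about 0.5%
  at the 1% default, with $\tau$ compensating by a few times that). The
  bias shrinks proportionally with the threshold — the unit tests verify
  both the bound and its tightening — and is partially masked by noise on
  real data. Method B is free of it, which is a quantitative argument for
  preferring the joint fit.
* **Usable range.** Walking the samples by increasing $X_W$,
  `detect_usable_range()` flags the first sample whose observed $R_{Wo}$
  falls more than `drop_tolerance` (default 5%; the drop is qualitative
  in the source system description, so a numeric default had to be chosen)
  below the fitted prediction, or whose per-detector primary rates diverge
  by more than the same tolerance; everything at or beyond that $X_W$ is
  out of range. Because a fit contaminated by post-saturation samples can
  make the whole low-rate series look deviant, `calibrate()` trims
  violating samples from the top of the $X_W$ range one step per
  iteration, refitting until the retained set is self-consistent.
  At quantification time the observed wide rate of a saturated acquisition
  folds *back below* the usable maximum, so a rate ceiling alone cannot
  flag it; when the true activity is known (accuracy studies), the same
  model-shortfall criterion is applied per sample.
* **Segmentation.** Threshold masks use an inclusive comparison
  (ties at exactly the threshold are kept, so the maximum voxel always
  survives and the operation is idempotent). ROI discs include a voxel if
  its centre lies within the radius — matching clinical ROI tools and
  reproducible across implementations — with coordinates in mm from the
  volume corner and 1-based slice indices.
* **Decay.** Known activities are decayed with a ¹⁷⁷Lu half-life of
  6.6443 d, applied in bookkeeping only (the camera model never sees it).

## What the simulator emulates

`generate_series()` produces serial acquisitions from a ground-truth
camera (`camera_truth()`: per-detector $CF$, one $\tau$, saturation rate,
per-detector post-saturation decay, optional pile-up constant) and phantom
(`phantom_truth()`: per-window spectral fractions, spurious-background
level, simple source/medium geometry). The baseline generative model
satisfies the wide-spectrum loss model *exactly*: the total true rate
$k_6\,CF\,A$ (with $k_6$ the geometry's wide-spectrum/primary ratio)
drives a single paralysable loss shared by all windows, and the photopeak
window holds primary plus local scatter such that TEW subtraction returns
the observed primary rate exactly in expectation. This separates
model-fidelity tests (noise-free recovery is exact to machine precision)
from robustness tests, where the layers on top break the idealization:

* Poisson noise on per-window counts (never Gaussian noise on rates);
* ¹⁷⁷Lu decay of the known activities across a plan;
* pile-up: a fraction $1 - e^{-R_{Wt}\,\tau_p}$ of surviving primaries is
  displaced from the photopeak into the upper-scatter and first
  general-scatter windows, conserving the 6W total;
* saturation: beyond an observed wide rate of 350 kcps the per-detector
  sensitivity decays exponentially in the fractional excess, detector 2
  about twice as fast as detector 1 (the drop is sharp, as on real systems
  that prioritize one detector at high rate);
* reconstructed volumes receive diffuse spurious background counts in
  dense non-radioactive medium, relatively stronger at low count rate,
  emulating residual-scatter artefacts that inflate whole-volume
  sensitivity and motivate threshold/ROI segmentation.

Default truth values ($CF = 9.36$ cps/MBq, $\tau = 0.550\ \mu s$,
saturation 350 kcps) and the default plan (17 activities spaced
geometrically over 19 MBq–15.1 GBq, 60-s frames) are chosen so simulated
count-rate magnitudes match a real ¹⁷⁷Lu calibration campaign on a
dual-head NaI system; phantom spectral fractions are set so the
wide-spectrum/primary ratios bracket the range from sources in air
($k_6 \approx 3.9$) to a large water-filled cylinder ($k_6 \approx 7.8$).

What the simulator does **not** emulate: photon transport (no collimator
septal penetration, no energy-resolution blur, no genuine spectra),
reconstruction noise texture and artefacts beyond the diffuse background
term, attenuation and partial-volume effects in volumes, and any
time-variation of $\tau$. Passing recovery tests therefore demonstrate
that the estimators are correct and robust *under the stated generative
assumptions*, not that a physical camera obeys them; on real data the
model adequacy itself (constant spectral ratio within a geometry,
paralysable behaviour below saturation) is an empirical matter.

```{r example}
camera  <- camera_truth()
phantom <- phantom_truth("CTDI-16")
records <- generate_series(camera, phantom,
                           default_planar_plan(seed = 42))
calibrate(records, method = "B", combination = "6W")
```

## Validation studies and problem sizes

The test suite exercises, among others:

* exactness of noise-free recovery (Method B, machine precision) and the
  bounded Method A bias discussed above;
* parameter recovery over 20 seeded Poisson replicates of the default
  planar scenario (median $CF$ error below 1%, median $\tau$ error below
  3%);
* geometry independence: with two phantoms whose $k_6$ differ twofold,
  photopeak-driven $\hat\tau$ differ by tens of percent while 6W-driven
  $\hat\tau$ agree within three combined standard errors;
* segmentation: on volumes with simulated spurious background,
  threshold-segmented rates yield a $CF$ strictly closer to truth than
  whole-volume rates (10 activities, 48×48×32 volumes);
* inversion: Lambert-W against an independent bisection oracle to
  $10^{-9}$ relative over a 1000-point grid.

These sizes keep the full suite in the order of seconds while leaving all
effects far above numerical tolerance.

## Known limitations

* Method A's $CF$ bias at the default dead-time-free threshold is
  structural (see above); use Method B, or a tighter `dt_threshold`, when
  sub-half-percent agreement matters.
* `detect_usable_range()` needs the saturation drop to exceed
  `drop_tolerance` at the sampled activities; a grid that lands a sample
  marginally past saturation leaves a residual (sub-tolerance) distortion
  in the retained set.
* The spurious-background term is phenomenological; it reproduces the
  direction and rate-dependence of reconstruction background, not its
  spatial statistics.
* Per-projection (angle-dependent) dead time and non-paralysable or
  hybrid detector models are out of scope.
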
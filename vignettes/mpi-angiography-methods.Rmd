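---
title: "Simulated MPI angiography: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated MPI angiography: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpiangio)
```

## What this package simulates

Magnetic particle imaging (MPI) maps the 3D distribution of
superparamagnetic iron-oxide nanoparticles by exploiting their nonlinear
magnetization response. A static selection gradient creates a field-free
point (FFP); three orthogonal sinusoidal drive fields sweep the FFP along a
3D Lissajous trajectory, and only particles near the instantaneous FFP
respond dynamically. The received voltage, decomposed into frequency
components, is related to the voxel-wise tracer concentration through a
calibration ("system function") matrix, and a regularized Kaczmarz solver
inverts each frame.

`mpiangio` implements this chain end to end for a concrete preclinical
scenario: first-pass angiography of the two large abdominal vessels of the
rat — inferior vena cava (IVC) and abdominal aorta (AA) — after an
intravenous tracer bolus. Because raw in-vivo data of this kind are not
publicly available, the package pairs every analysis step with a synthetic
data generator whose ground truth is known exactly, so the quantitative
endpoints (concentration-time curves, digital subtraction angiography,
lumen diameters, respiratory biosignal, visual-grading statistics) can be
validated rather than merely exercised.

## Scanner model

The default `scanner_config()` encodes a 25/20-class FFP scanner:

* drive frequencies: 2.5 MHz divided by 102 / 96 / 99 (x / y / z), i.e.
  24.51 / 26.04 / 25.25 kHz;
* drive amplitude 12 mT per axis; selection gradient 1.25 / 1.25 / 2.5 T/m;
* the FFP excursion per axis is A/G, so the drive FOV is
  2A/G = 19.2 x 19.2 x 9.6 mm;
* the Lissajous trajectory closes after LCM(102, 96, 99) = 53 856 base
  periods: 21.5424 ms per frame, hence floor(1/0.0215424) = 46 whole
  volumes per second. The exact period, not the rounded rate, drives all
  timing.

Magnetization follows the equilibrium Langevin law
$L(\xi) = \coth \xi - 1/\xi$ with $\xi = m B / (k_B T)$ at $T = 300$ K and
per-particle moment $m = M_s \pi d^3/6$. The series
$\xi/3 - \xi^3/45$ replaces the closed form for $|\xi| < 10^{-4}$ to avoid
cancellation. Relaxation (Brownian/Néel) dynamics, coil inhomogeneity and
the receive-chain transfer function are deliberately out of scope; the
receiver is one idealized channel per axis. Drive-field phase offsets
default to zero and are configurable.

## Tracers

Two presets bracket the tracer space:

* `tracer_mcp3()` — a multicore particle with a single effective 32 nm
  core population, 53 nm hydrodynamic diameter, stock 145.5 mmol Fe/l.
  Its blood half-life is dose-dependent (8.8 min at 0.05, 17.4 min at
  0.1 mmol Fe/kg); the preset selects the value measured at the nearer
  dose.
* `tracer_resovist()` — a bimodal 4/16 nm number-fraction mixture
  (default 30% 16 nm cores), 60 nm hydrodynamic diameter, stock
  500 mmol Fe/l, half-life 4.85 min (midpoint of the published
  3.9–5.8 min MRI range).

Each population contributes in proportion to the iron it carries (number
fraction times $d^3$), so the 16 nm minority dominates the bimodal signal
(97% of the iron). At 12 mT the 32 nm cores reach $\xi \approx 17$ — deep
saturation — which is why their harmonic spectrum decays slowly, whereas
the small-core mixture rolls off quickly. `harmonic_spectrum()` makes this
contrast explicit; the 9th/3rd-harmonic amplitude ratio of the multicore
model exceeds the bimodal model's by two orders of magnitude, the
mechanism behind its better image quality at equal dose.

## Phantom and bolus kinetics

`default_rat_phantom()` builds two parallel grid-aligned cylinders spanning
the long in-plane axis: IVC 2.7 mm and AA 2.4 mm lumen diameter, centerlines
3.5 mm apart, inside a 259 ± 19 g virtual animal (body weight drawn once per
seed). Partial-volume rasterization uses 5× supersampling per axis; the
rasterized cross-section converges to $\pi r^2$ within 2% for lumina at
least two voxels wide.

The bolus model is a gamma-variate first pass plus a recirculation term,
all damped by monoexponential clearance:

$$c(t') = A\,\Big[(t'/t_p)^\alpha e^{\alpha(1 - t'/t_p)}
  + r\,(1 - e^{-t'/\tau})\Big]\; 2^{-t'/T_{1/2}}$$

with $t'$ the time since bolus arrival in that vessel. Defaults: arrival
delays 1.25 s (IVC) and 2.5 s (AA) after injection, time-to-peak
$t_p = 1$ s, shape $\alpha = 2.5$, recirculation fraction $r = 0.25$ with
mixing time $\tau = 15$ s. The gamma-variate shape is the standard choice
in bolus-tracking angiography; the width is a free parameter because
manual injections have no defined duration. Peak amplitudes derive from
the dose: the blood-pool equilibrium concentration is
dose × body weight / blood volume (64 ml/kg), times a first-pass factor of
5 (IVC) or 3 (AA, after cardiopulmonary transit). These factors are
order-of-magnitude physiology, not fitted constants; every endpoint the
package validates (peak timing, diameters, spectra, statistics) is
insensitive to them.

Respiration multiplies the *simulated signal amplitude* by
$1 + \delta \sin(2\pi f_r t)$ (default 60 breaths/min, depth
$\delta = 0.1$); it does not deform the geometry. This is a proxy for
organ motion sufficient to carry a realistic respiratory biosignal into
the raw data, and deliberately nothing more.

## Forward model and calibration

`simulate_system_matrix()` simulates, for every voxel center, one Lissajous
period of the magnetization of a point sample in the field
$B_i(t) = G_i (r_i - \mathrm{ffp}_i(t))$, differentiates in time via the
spectral derivative, and stores the Fourier components (per receive axis)
as the voxel's column. Matrix entries are scaled to the response of a voxel
filled at the calibration concentration (default 100 mmol Fe/l, explicitly
configurable, since vendor calibration details are generally unpublished).
Signal synthesis is then linear:
frames = respiration × S c / c\_cal + background + complex Gaussian noise.

Numerical choices that matter:

* **Temporal sampling.** The default for desk-scale grids is 4096 samples
  per period. The informative "mixing" components cluster around the
  drive-frequency harmonics (indices k ≈ 528–561 for the fundamentals,
  ~1056–1683 for the 2nd/3rd harmonic bands); 4096 samples keep all of
  them below Nyquist. 1024 samples — usable for plumbing tests — alias the
  fundamentals away and visibly degrade resolution.
* **Fundamental exclusion.** Components exactly at the three drive
  frequencies are dropped by default: on real hardware they are dominated
  by direct feedthrough, and they carry almost no spatial encoding while
  distorting any SNR-based retention scale.
* **Component retention.** `retain_components()` keeps components whose
  calibration SNR (max response over voxels / noise SD) exceeds 2, capped
  at a configurable count (pipeline default 600). A threshold of 5 was
  evaluated and discards mixing components that still carry useful
  encoding at moderate noise, inflating diameter errors several-fold; 2 is
  therefore the package default. The threshold is exposed because no
  published value exists for the vendor chain.

## Reconstruction

`kaczmarz_tikhonov()` solves
$\min_c \lVert S c - u \rVert^2 + \lambda \lVert c \rVert^2$ by row action
on the lifted consistent system $[S \;\; \sqrt{\lambda} I]$, complex
components stacked as separate real rows, with an optional non-negativity
projection after each sweep. Convergence is declared by sweep count, never
by tolerance, so every run is bit-reproducible. Imaging defaults (λ =
10⁻³ × mean squared row norm, 10 sweeps, rows ordered by descending SNR,
non-negativity on) match common MPI practice.

Two properties shape the tests: (i) iterates contract monotonically toward
the Tikhonov solution *in the lifted space* — the plain data residual is
not monotone for cyclic sweeps and is not asserted to be; (ii) the lifted
system's smallest singular value is $\sqrt{\lambda}$, so demonstrating
1 × 10⁻⁴ agreement with the dense closed-form solve requires a moderate
λ (0.05 × mean squared row norm) and a few thousand sweeps. The oracle
tests use exactly that regime; quantitative diameter readouts use 50
sweeps.

Reconstructed concentrations convert to micrograms of iron per voxel via
µg = c [mmol/l] × voxel volume [l] × 55.845 [g/mol] × 10³ — a 1 mmol/l
voxel of 0.8 × 0.8 × 0.4 mm holds 0.0143 µg. `overscan_crop()` restricts a
volume to voxel centers strictly inside the drive FOV; for the full
33³-voxel / 26.4 × 26.4 × 13.2 mm geometry that interior box is 23³ voxels
(the grid is odd and centered, so exactly 23 centers per axis fall inside).

## Quantitative angiography

The analysis chain mirrors the clinical workflow: a VOI mean per frame
gives concentration-time curves; t₁ is the IVC peak frame (a configurable
offset is available because "a single frame during bolus passage" does not
pin the exact choice) and t₂ the AA peak frame, with a bolus accepted only
if it rises 3 baseline SDs above the pre-injection level. Digital
subtraction (volume(t₂) − volume(t₁), negatives clipped — concentrations
are physical) cancels the venous signal and isolates the arterial phase.

Vessel cross-sections are segmented per transverse slice at 30% of the
*slice* maximum (per-slice normalization is robust to bolus decay along
the vessel; a global-max mode exists), restricted to the 8-connected
component containing the maximum so the adjacent vessel cannot merge into
the mask. Cross-sectional area is pixel count × pixel area and
$D_L = 2\sqrt{A/\pi}$ under the circular assumption. Along the vessel
axis, slices whose maximum falls below 10% of the volume maximum are
considered outside the vessel-bearing segment.

Partial-volume behaviour is worth stating precisely: on noiseless
rasterized cylinders of 2–3 mm at 0.8 mm in-plane voxels with the
centerline through voxel centers, the estimator is accurate to ±0.4 mm;
shifting the centerline by half a voxel changes the estimate by up to
~0.6 mm. The bias direction is stable across seeds but its size depends on
sub-voxel placement — the same caveat that applies to the in-vivo
measurement, where the quoted diameters are relative, not absolute. With
reconstruction in the loop (15 × 15 × 7 grid, peak component SNR 20) the
recovery stays within ±0.8 mm across diameters and noise seeds.

## Biosignal and statistics

The respiratory biosignal is the per-frame magnitude of one raw component
(default: the strongest), detrended with a 2.5 s centered moving average —
the bolus passage and clearance dominate the spectrum at low frequency —
Hann-windowed, and turned into a periodogram. The dominant frequency is
the argmax above 0.4 Hz (24 breaths/min), the lower edge of the
physiological band for anesthetized rats; in the pipeline the estimate is
additionally computed on the post-first-pass plateau, where the modulation
is not masked by the transient. All three choices (window, band edge,
analysis window) are parameters.

The clearance check that gates a repeat injection passes only when the
respiratory-band periodogram power stays within 3× a tracer-free reference
and the mean component magnitude stays within 3 SD of the empty-bore
level; five half-lives after a bolus (3.1% residual) it passes again at
the default thresholds.

Visual-grading (VGAS) scores are ordinal human input: the package
validates the 1–4 range, forms the per-examination overall score (sum of
three criteria, 3–12), and compares tracers with a one-tailed Mann-Whitney
U test (alternative fixed as multicore > conventional). For combined
n ≤ 12 the p value is exact by enumeration of all labelings with midrank
ties; beyond that a tie-corrected normal approximation with continuity
correction is used. At n = 3 vs 3 the smallest attainable exact p is
1/C(6,3) = 0.05, exactly the conventional significance threshold — worth
remembering when reading such comparisons.

## Pipeline, container and problem sizes

`run_pipeline()` executes the whole chain deterministically from one seed
and can persist every stage in a run container: a directory with
MDF-inspired group names (`acquisition`, `calibration`, `measurement`,
`truth`, `reconstruction`, `analysis`), raw little-endian doubles for
arrays and JSON manifests for structure. Round trips are bit-exact and a
schema version gates readers.

The default desk-scale examination uses a 15 × 15 × 7 grid over
13.2 × 13.2 × 6.6 mm (0.88 mm in-plane voxels), 4096 samples per period,
20 s of acquisition at every 4th frame, and a peak component SNR of 100 —
typical of in-vivo bolus imaging with a dedicated receive coil. Component
retention in the pipeline is referenced to the clean peak-bolus frame
(components whose measured amplitude clears twice the noise are kept, up
to 600): with an extended object the measured spectrum decays faster than
the calibration row maxima, so measurement-referenced retention reflects
the information actually present in the data. These sizes let a full
examination simulate in about a minute on one core while preserving the
physics that matters (drive harmonic bands, partial-volume effects,
realistic noise). The full 33³ / 53 856-sample geometry is supported but
generated only on demand.

## What passing tests do and do not show

The generator reproduces the experimental conditions it targets: vessel calibers and
spacing, arrival delays, clearance half-lives, respiratory modulation near
1 Hz, receive noise, a static background. It does not model cardiac
pulsation, vessel branching, relaxation dynamics, coil sensitivities, or
scanner drift. Consequently the tests demonstrate that the *analysis
chain* is correct and well-calibrated on data whose ground truth is known
— e.g. that the diameter estimator's partial-volume bias, not the solver,
limits accuracy — but they cannot certify in-vivo accuracy, and the
package makes no claim to reproduce in-vivo VGAS scores or
diameter tables, which require the original raw data.
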
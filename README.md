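# mpiangio

Simulation and quantitative analysis of magnetic particle imaging (MPI)
angiography of the rat abdomen.

MPI maps the 3D distribution of superparamagnetic iron-oxide nanoparticles
through their nonlinear magnetization response: a selection gradient **G**
creates a field-free point (FFP), three sinusoidal drive fields of
amplitude **A** sweep the FFP along a Lissajous trajectory, and the
received frequency components **u** relate to the voxel-wise tracer
concentration **c** through a calibration (system-function) matrix **S**.
Reconstruction solves the Tikhonov-regularized least-squares problem

    c* = argmin_c || S c - u ||^2 + lambda || c ||^2,   c >= 0

with a row-action (Kaczmarz) solver, frame by frame at 46 volumes/s.

The package is written for imaging scientists who want to study the MPI
angiography analysis chain — volume-of-interest concentration–time curves,
digital subtraction angiography (DSA), 30%-threshold vessel segmentation,
lumen diameter D_L = 2·sqrt(area/pi), respiratory biosignal extraction,
and visual-grading (VGAS) rank statistics — against synthetic data with
exactly known ground truth, since raw in-vivo MPI data of this kind are
not publicly available. Every stage is a tested package function:

| stage | functions |
|---|---|
| scanner physics | `scanner_config`, `lissajous_period`, `frame_rate`, `fov_extent`, `ffp_position`, `langevin` |
| tracers & phantom | `tracer_mcp3`, `tracer_resovist`, `default_rat_phantom`, `bolus_concentration`, `concentration_map` |
| forward model | `simulate_system_matrix`, `simulate_signal`, `harmonic_spectrum`, `subtract_background` |
| reconstruction | `kaczmarz_tikhonov`, `tikhonov_dense`, `reconstruct_series`, `overscan_crop` |
| angiography | `concentration_time_curve`, `select_timepoints`, `digital_subtraction`, `segment_vessel`, `lumen_diameter`, `measure_vessel` |
| biosignal & stats | `extract_biosignal`, `respiratory_rate`, `clearance_check`, `mann_whitney_one_tailed`, `vgas_summary` |
| orchestration | `validate_config`, `run_pipeline`, `write_run_container`, `read_run_container` |

## Worked example

A complete simulated examination — two-vessel rat phantom (IVC 2.7 mm, AA
2.4 mm lumen), multicore tracer at 0.1 mmol Fe/kg, bolus injected at 4 s,
system-function calibration, noisy raw signal with respiratory modulation,
background subtraction, per-frame reconstruction and the full quantitative
analysis — runs from one seed:

```r
library(mpiangio)
run <- run_pipeline(seed = 1)
print(run)
#> Simulated MPI examination
#>   frames: 233, components: 136, grid: 15x15x7
#>   bolus: t1 = 6.38 s, t2 = 8.01 s
#>   AA lumen: 2.12 +/- 0.55 mm (15 slices)
#>   IVC lumen: 3.33 +/- 0.27 mm (15 slices)
#>   respiratory rate: 56.5 breaths/min
```

Reading the numbers: the bolus peaks in the IVC ~2.4 s after the 4 s
injection (t1) and the arterial phase peaks later (t2), consistent with
the simulated arrival delays of 1.25 s and 2.5 s plus the 1 s bolus
time-to-peak and dispersion. The lumen diameters (truth: IVC 2.7 mm, AA
2.4 mm) are measured on ~0.9 mm voxels with a 30%-of-slice-maximum
threshold, which carries a partial-volume bias of up to roughly one voxel
in either direction (see the methods vignette). The respiratory rate
recovers the simulated 60 breaths/min to within one spectral bin of the
analysis window.

The tracer contrast at the heart of the comparison — multicore 32 nm cores
versus a bimodal 4/16 nm mixture — shows up directly in the harmonic
spectrum:

```r
cfg <- scanner_config()
harmonic_spectrum(tracer_mcp3(), cfg)$normalized[9]      # 0.529
harmonic_spectrum(tracer_resovist(), cfg)$normalized[9]  # 0.0025
```

The 9th/3rd-harmonic ratio is ~200x larger for the multicore model: its
high harmonics survive, so it images better at equal dose.

The numbered scripts under `analysis/` run the full examination workflow
(scanner characterization, three simulated examinations, DSA and lumen
quantification, biosignal extraction, VGAS statistics) and write their
tables under `results/`.

## Limitations

The simulator omits cardiac pulsation, vessel branches, Brownian/Néel
relaxation and receive-coil characteristics; lumen diameters carry the
same partial-volume caveats as the in-vivo measurement. In-vivo VGAS
scores and in-vivo diameter tables are not recomputable without the
original raw data and are not claimed. See
`vignettes/mpi-angiography-methods.Rmd` for the full model description and
design rationale.
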
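# gradstim

Cardiac magnetostimulation (CS) safety ratios for MRI gradient coils, at
desk scale.

## The problem

Switched gradient fields induce electric fields in the patient. IEC
60601-2-33 protects the heart by limiting dB/dt on a compliance cylinder
(radius 0.20 m along the bore), using the strength–duration law

```
E     <  E_rheo   / (1 - exp(-tau_s,eff / tau_c)),   E_rheo   = 2 V/m
dB/dt <  dBdt_rheo / (1 - exp(-tau_s,eff / tau_c)),  dBdt_rheo = 20 T/s
```

with chronaxie `tau_c = 3 ms` and `tau_s,eff` the peak-to-peak field
variation divided by the maximum field derivative (twice the rise time for
a bipolar trapezoid). The factor connecting the two limits is the
**dB/dt-over-E-field conversion ratio** (historically 10 (T/s)(V/m)⁻¹, from
a homogeneous-ellipsoid calculation). This package re-implements the full
simulation chain used to re-evaluate that ratio in heterogeneous bodies:

1. **phantoms** – synthetic voxel torsos with a myocardial shell
   (σ = 0.385 S/m), blood pool (0.662 S/m) and lungs (0.101 S/m); seeded
   populations spanning heights 1.53–1.90 m and weights 52–120 kg.
2. **coils** – Maxwell-pair (z) and Golay-saddle (x/y) wire-loop gradient
   coils with concentric shields; exact finite-segment Biot–Savart B and
   vector potential A; gradient efficiency `G_eff`; peak dB/dt over the
   IEC compliance volume, scaled by `slew / G_eff`.
3. **em_solver** – magneto-quasistatic scalar potential on the voxel grid:
   `div(sigma (grad phi + dA/dt)) = 0` (7-point stencil, harmonic-mean face
   conductivities, Jacobi-PCG to 1e-8), then `E = -dA/dt - grad phi`.
4. **field_metrics** – nearest-rank percentile metrics Emax/E99.9/E99/E95 of
   myocardial |E|, percentile threshold masks and single-layer erosion: the
   machinery that suppresses voxel *staircasing* outliers at conductivity
   interfaces.
5. **sweep_pipeline** – landmark sweeps along z, worst-case-per-metric
   extraction, and ratio tables `ratio = peak_dBdt / E_metric` over
   model × coil × axis studies.
6. **risk_model** – Reilly's log-normal threshold distribution (median
   12 V/m, 1st percentile 6 V/m), its product-convolution with ratio
   distributions, adverse-event probabilities and the IEC limit curves.

## Worked example

The historical validation scenario — a conducting cylinder of radius 0.2 m
in a uniform axial field switched at 100 T/s — has the closed form
`|E| = (r/2) dB/dt`, i.e. 10 V/m at the rim:

```r
library(gradstim)
cyl <- make_homogeneous_cylinder(0.2, 0.2, 0.01, sigma = 0.2,
                                 resolution = 4, myocardium = "all")
src <- make_ideal_field("uniform_B", 1)
drv <- drive_spec(slew = 100)        # read as dB/dt = 100 T/s here
da  <- dAdt_grid(src, cyl, drv)
phi <- solve_scalar_potential(cyl, da)
E   <- compute_E(phi, da, cyl)
metric_set(E, cyl$masks$myocardium)
#> metric_set: Emax 11.53 | E99.9 11.53 | E99 10.27 | E95 9.513 V/m (n = 15720)
```

Emax overshoots the closed form: rim voxels carry the staircasing artifact
(it does *not* shrink with resolution), while E99/E95 sit near the analytic
area-fraction values 9.95 and 9.75 V/m — the reason percentile metrics are
used at all. The conversion ratio and the risk numbers:

```r
peak <- compliance_peak_dBdt(src, drv,
                             compliance_volume(z_extent = c(-0.1, 0.1)))
compute_ratio(peak, percentile_metric(E, cyl$masks$myocardium, 99))
#> [1] 9.73546            # the classic "ratio of 10" scenario

d <- calibrate_lognormal()           # median 12 V/m, 1st percentile 6 V/m
prob_E_below(d, 2) * 1e9
#> [1] 0.9076763          # ppb at the 2 V/m rheobase: under the 10 ppb bound
iec_dBdt_limit(c(0.45, 3, 1000))
#> [1] 143.58325  31.63953  20.00000   # T/s
effective_stimulus_duration(waveform_bipolar_trapezoid(0.5e-3, 1e-3))
#> [1] 0.001               # s: twice the 0.5 ms rise time
```

A full synthetic study (population of bodies × gradient sets × landmark
sweep) is driven by `run_study()`; see `?run_study` and the methods
vignette (`vignettes/gradstim-methods.Rmd`).

## Command line

A thin CLI over the same functions ships in `inst/cli/gradstim`
(`phantom make`, `coil make`, `coil dbdt`, `solve`, `sweep run`,
`risk limit|tau|prob`).
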
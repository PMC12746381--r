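---
title: "Methods: simulating cardiac dB/dt-over-E-field safety ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating cardiac dB/dt-over-E-field safety ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

MRI gradient switching induces electric fields in conducting tissue; the
cardiac stimulation (CS) limit in IEC 60601-2-33 caps dB/dt on a 20 cm
radius compliance cylinder, with the cap derived from an E-field rheobase
of 2 V/m through a dB/dt-over-E-field conversion ratio. `gradstim`
implements the full desk-scale chain for estimating such ratios in
heterogeneous bodies and for propagating them into adverse-event
probabilities. Everything is synthetic and parameterized: the package's
purpose is to make every stage of the method testable, not to reproduce
any particular licensed anatomy or proprietary coil.

The electromagnetic regime is magneto-quasistatic: at ~1 kHz and tissue
conductivities below 1 S/m, displacement currents and induced-field
back-reaction are negligible, so the induced field is

$$\mathbf{E} = -\partial_t \mathbf{A} - \nabla\varphi, \qquad
  \nabla\cdot\big(\sigma(\nabla\varphi + \partial_t\mathbf{A})\big) = 0,$$

with $\mathbf{A}$ the source vector potential of the coil and zero normal
current on the body surface. Conductivity is real, so E is in phase with
dB/dt and all computations are done with real arithmetic at the instant of
peak slew. For a sinusoidal drive of amplitude $I_0 = S/(\omega G_{eff})$,
peak $\partial_t\mathbf{A} = \mathbf{A}_{unit}\, S/G_{eff}$: the frequency
cancels, which is why every conversion ratio in this package is
frequency-independent and why the 1 kHz figure only matters for effective
stimulus durations. Fields are reported as peak-of-sinusoid (not RMS);
ratios are insensitive to that choice as long as numerator and denominator
use the same convention.

## Synthetic bodies (`phantoms`)

A body is an elliptical-cylinder torso of bulk tissue (default 0.23 S/m —
a free choice documented here; roughly a muscle/fat average) containing
two lung ellipsoids (0.101 S/m) and an ellipsoidal myocardial shell
(0.385 S/m) around a blood pool (0.662 S/m) — the three conductivities
that drive staircasing at cardiac interfaces. Voxels take the innermost
shape containing their center (blood > myocardium > lung > torso); this
center-point rule deliberately reproduces hexahedral staircasing, the
artifact under study. Grids are uniform and isotropic (0.5–5 mm sweep
range); the adaptive meshes of production solvers are out of scope.

Two default worlds:

* `body_params()` — the *standard chest-section phantom*: torso
  0.09 × 0.065 × 0.18 m with a full-size heart (outer semi-axes
  40 × 34 × 42 mm, wall 8 mm). Full-size cardiac geometry keeps the
  myocardial shell at least one voxel thick up to 5 mm resolution, while
  the shortened torso keeps the 1 mm grid at ~3.3 M conducting voxels,
  solvable in ~3 minutes on one CPU.
* `body_params_from_anthropometry(height, weight)` — full-length torsos
  for population studies: torso length 0.30 × height; cross-section from
  weight at density 1050 kg/m³ with 45% of body volume in the torso and a
  0.7 transverse aspect ratio; heart linear in height about a 1.70 m
  reference. Populations (`make_population()`) draw uniformly from stated
  ranges (heights 1.53–1.90 m, weights 52–120 kg) with a seeded RNG —
  uniform because the source material gives ranges, not distributions.

Lung x-placement is derived so the lung tip reaches mid-wall depth of the
myocardium: the myocardium–lung conductivity interface then exists at
every resolution and heart scale. Lungs may overlap the *shell* (label
precedence resolves the voxel); a lung reaching the *blood pool* is a
geometry conflict and errors. `heart_scale` enlarges the heart (semi-axes
and wall), scaling myocardial volume with its cube — the cardiomegaly
manipulation.

What the generator does **not** emulate: realistic organ shapes, fat/bone
layering, ~90-class tissue maps, postures, pregnant anatomy. A green test
therefore establishes properties of the *method* (solver correctness,
metric robustness, pipeline invariants), never clinical ratio values; the
headline worst-case ratios of the production studies depend on proprietary
inputs and are explicitly out of scope.

## Coils (`coils`)

Gradient coils are sets of closed wire polylines with signed currents.
B and A use exact finite-straight-segment closed forms (Coulomb gauge),
summed over segments — no quadrature; circles are discretized at ≥ 72
segments (center-field error ~0.06%). The numerically stable forms are

$$\mathbf{B} = \frac{\mu_0 I}{4\pi}
   \frac{(\hat u \times \mathbf r_1)}{d^2}
   \left(\frac{s_1}{R_1} - \frac{s_2}{R_2}\right), \qquad
  \mathbf{A} = \frac{\mu_0 I}{4\pi}\,\hat u\,
   \ln\frac{R_1 + R_2 + L}{R_1 + R_2 - L}.$$

Evaluation within 1 mm of a wire raises a singular-evaluation error naming
the loop.

Presets (winding patterns are package plumbing — production windings are
proprietary): a Maxwell pair for z (half-separation $\sqrt{3}R/2$, the
optimal-linearity spacing) and a four-saddle Golay family for x/y (120°
arcs; inner arcs at 0.35 of the half-length; the y coil is the x coil
rotated 90° about z). `shielded = TRUE` adds a geometrically scaled copy
of the winding at 1.25× the primary radius carrying current
$-I(R/R_s)^3$, cancelling the leading far-field multipole (verified as a
pointwise stray-field reduction at twice the primary radius). The
`inner_diameter`/`length` metadata are constrained to the realistic ranges
0.64–0.92 m and 1.06–1.60 m unless overridden.

Ideal sources bypass Biot–Savart in validation: `uniform_B` has
$\mathbf A = \tfrac{B_0}{2}(-y, x, 0)$ with $\nabla\times\mathbf A$
exactly $(0,0,B_0)$. `uniform_gradient` is subtler: a pure $(0,0,Gz)$
field is not divergence-free, so its A,
$\tfrac{G}{2}(-yz, xz, 0)$, necessarily carries transverse curl components
$(-Gx/2, -Gy/2, 0)$. The source's *reported* B is the idealized gradient
term $(0,0,Gz)$ only — that makes the compliance-volume example (peak
dB/dt = slew × z_max) exact, at the documented cost that the reported B is
the gradient part, not the full curl of A.

Peak dB/dt over the compliance volume is
$\max |\mathbf B_{unit}| \times S/G_{eff}$ on a cylinder grid (1 cm
spacing, z-extent defaulting to the coil wire extent); it is invariant to
the coil current amplitude since the current cancels in
$|\mathbf B|/G_{eff}$. Simultaneous X+Y+Z drive uses an in-phase
root-sum-square split, $S/\sqrt 3$ per axis (the split and phase are not
dictated by the source material; the rule is a named, swappable
convention).

## Scalar-potential solver (`em_solver`)

Cell-centered potentials on conducting voxels; 7-point stencil with
harmonic-mean face conductivities, so a face with a zero-σ neighbor
carries zero flux — the insulating boundary emerges naturally and the
system is symmetric positive semi-definite. Jacobi-preconditioned
conjugate gradients to a relative residual of 1e-8 (configurable);
disconnected conductor components get independent mean-zero constraints
(components from a 6-connected BFS). dA/dt for wire coils is evaluated on
a coarse 8 mm auxiliary lattice and interpolated trilinearly (A is smooth
away from the windings; the lattice is shared across all landmarks of a
sweep); ideal sources are evaluated exactly.

E is reconstructed at voxel centers as the mean of the two face gradients
per axis; at insulating faces the face gradient is $-\partial_t A$ so the
normal E vanishes there. Consequently "φ = 0 ⇒ E = −dA/dt" holds exactly
on interior voxels, while boundary voxels blend in the zero-normal
convention. A discrete current-conservation residual (max net cell current
over interior cells / mean face current) serves as diagnostic: at
solver-tolerance level for converged solves, large when the potential term
is omitted.

**Staircasing, quantified.** The discrete insulating boundary is a jagged
polygon whose step corners carry field singularities; voxels adjacent to
the boundary overshoot by a resolution-*independent* amount. On the
homogeneous elliptical cylinder (a = 0.2 m, b = 0.125 m, uniform
100 T/s; closed-form max 8.99 V/m at (0, ±b)) we measure global rim Emax
of 9.8 / 10.1 / 10.6 V/m at 4 / 2 / 1 mm — the overshoot *grows* slightly
with resolution, matching the known behavior of hexahedral solvers. The
solver oracle is therefore evaluated on the `"interior"` myocardium region
(conductor scaled by 0.95, a fixed physical margin from the air boundary —
the analogue of a heart that never touches the body surface): there the
solver max converges to the closed-form max over the same region (2.1% at
2 mm, 0.13% at 1 mm). Inside the body, tissue–tissue interfaces
(myocardium–lung, myocardium–blood) show |E| jumps exceeding 10% at 1–2 mm
— the substrate for the percentile metrics.

## Percentile metrics (`field_metrics`)

Nearest-rank percentiles: sort masked |E| ascending, return the value at
rank $\lceil pN/100\rceil$. The convention is interpolation-free so
removal counts are integers: thresholding at E99 removes
$N - \lceil 0.99N\rceil$ voxels for distinct values — exactly 1%
(3000 of 300 000, the typical 1 mm heart). Ties at the threshold are kept
(strictly-above removal), so a constant field loses nothing. The
alternative mitigation, single-layer 6-connected erosion, removes a
resolution-dependent fraction (~3/R of a radius-R-voxel ball) and is
provided for comparison; metrics operate on |E| only.

## Sweeps and ratios (`sweep_pipeline`)

Landmarking translates the *body* along z (coil and compliance volume
fixed — equivalent to table motion); the body-attached grid means the
system matrix is built once per model and reused across coils, axes and
landmarks. Per landmark the myocardial metric set is computed; the
worst-case landmark is selected per metric independently (the source
material does not specify which metric defines the worst case; selecting
per metric is conservative for each), ties toward smaller |z|. The
worst case colocates with the argmax of mean |B| over the heart volume
(the "coil eye" for transverse coils), asserted in tests against an
exhaustive Biot–Savart profile. Each (model, coil, axis) worst case
contributes one ratio sample `peak_dBdt / E_metric`; aggregation reports
the minimum (worst case) and nearest-rank 0.1/1/10th percentiles.
End-to-end linearity makes every ratio invariant to the drive amplitude —
doubling the slew doubles both numerator and denominator bit-exactly, a
test of the whole chain.

## Risk model (`risk_model`)

Population CS thresholds are log-normal, calibrated by the median
(12 V/m) and the 1st percentile (6 V/m):
$\sigma_{\log} = \ln(12/6)/z_{0.99} = 0.297955$. The probability that an
individual's threshold lies below the 2 V/m rheobase is
$\Phi(\ln(2/12)/\sigma_{\log}) = 9.1\times10^{-10}$ — about 0.9 ppb,
under the 10 ppb design bound. "Convolution" with a ratio distribution is
the distribution of the product $R \times E$ (convolution in the log
domain). Two paths are kept deliberately: a seeded Monte-Carlo sample
(≥ 10⁴ draws) and the exact stratified mixture
$P(T \le t) = \tfrac1m\sum_i \Phi\!\big((\ln(t/R_i)-\mu_E)/\sigma\big)$,
whose closed-form strata stay accurate at the extreme tail probabilities
(10⁻⁹…10⁻¹⁵) where an empirical CDF truncates; the two agree to the
DKW envelope $3/\sqrt n$ for degenerate ratios. The IEC limit curves are
rheobase/(1 − exp(−τ/3 ms)); the effective dB/dt limit for a chosen
conversion ratio r is 2r T/s; the effective stimulus duration of a sampled
waveform is peak-to-peak value over max first-difference slope (≥ 20
samples per ramp recommended; exact for sampled linear ramps).

## Numerical choices and defaults

| Parameter | Default | Unit | Why |
|---|---|---|---|
| solver rel. tolerance | 1e-8 | – | residual diagnostic ≤ 1e-6 follows |
| voxel resolution (standard phantom) | 2 | mm | staircase visible, minutes-scale |
| torso bulk σ | 0.23 | S/m | free choice (documented) |
| slew | 100 | T/m/s | stated drive amplitude |
| landmark step / count | 0.05 / 41 | m / – | stated sweep (tests use fewer) |
| compliance radius / spacing | 0.20 / 0.01 | m | stated volume |
| segments per turn | 72 | – | 0.06% closed-form error |
| A-interpolation lattice | 8 | mm | smooth-field error ≪ solver error |
| shield radius ratio / current | 1.25 / −(R/Rs)³ | – | leading multipole cancels |
| threshold median / 1st pct | 12 / 6 | V/m | stated calibration |
| rheobase E / chronaxie | 2 / 3 | V/m / ms | stated limit constants |

Degenerate inputs: empty masks, non-positive E values, constant waveforms,
lungs penetrating the blood pool, < 8 voxels per semi-axis, shield radius
≤ primary, evaluation on a wire — all error early with specific messages.
Erosion emptying a mask warns and returns the empty mask.

## Known limitations

* Synthetic geometry only; absolute E-field levels are not clinical
  predictions and the production worst-case ratios (12–13 (T/s)(V/m)⁻¹)
  are not reproducible here by design.
* Uniform grids; no adaptive meshing, no anisotropic or dispersive tissue.
* Voxel Emax at staircased boundaries does not converge (by construction —
  it is the artifact under study); use E99/E95.
* The X+Y+Z combination rule (in-phase, RSS split) is a convention; other
  phase relationships would change combined-axis ratios.
* Landmark sweeps translate along z only; transverse offsets (reported
  elsewhere as ≤ 8% effects) are not part of the core pipeline.
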
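---
title: "Methods: diffusion tensor analysis of peripheral nerve compartments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diffusion tensor analysis of peripheral nerve compartments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nervedti)
```

## The problem

Peripheral nerves are built from fascicles — bundles of axons sheathed by a
thin perineurium — embedded in loose interfascicular epineurium. Water
diffusion inside fascicles is strongly anisotropic (fast along the fibre
axis, hindered across it), the perineurium is a diffusion barrier, and the
epineurium ex vivo shows slow, nearly isotropic diffusion. Diffusion tensor
imaging (DTI) at microscopy resolution can resolve these compartments in an
excised nerve segment and quantify each one's diffusion indices, which is
the analysis this package implements end to end: simulation of such an
acquisition, tensor estimation, per-compartment indices, fascicular
morphometry, the associated statistics, and streamline/ellipsoid displays.

## Signal model and tensor estimation

Each measurement follows the mono-exponential Stejskal–Tanner model

$$S_i = S_0 \exp(-b_i\, \hat g_i^{\mathsf T} D\, \hat g_i),$$

with $b$ in s/mm² and the symmetric tensor $D$ reported in
$10^{-9}\,\mathrm{m^2/s}$. Taking logs turns this into a linear system in
the six unique tensor components plus $\log S_0$; `build_design_matrix()`
assembles the standard seven-column design and `fit_tensor_lls()` solves it
by ordinary least squares. We use the *unweighted* log-linear estimator as
the default: it is the minimal, assumption-light choice, and a
signal-squared weighted variant (the first-order variance correction for
log-transformed magnitude data) sits behind `weighted = TRUE` for users who
want it. On noiseless data the two coincide; the tests verify recovery of
the generating tensor to $10^{-9}$ relative error.

Two fitting routes exist on purpose:

* **voxelwise** (`fit_dti_volume()`), which maps eigenvalues, FA, MD and
  $D_\parallel/D_\perp$ over the volume, and
* **region-averaged** (`fit_tensor_region()`), which averages the signal
  over a compartment's voxels *before* fitting a single tensor.

Averaging signals first is not a convenience but a statistical decision:
magnitude-MRI noise biases voxelwise tensor estimates (anisotropy is
inflated by the noise floor), while the mean signal over a few thousand
voxels is essentially noiseless. The test suite checks both the accuracy of
the region route at the calibrated noise level and the *positive* FA bias
of the voxelwise route relative to it.

From the eigenvalues $D_1 \ge D_2 \ge D_3$ the indices are

$$\mathrm{MD} = \tfrac{1}{3}(D_1+D_2+D_3), \qquad
\mathrm{FA} = \sqrt{\tfrac{3}{2}}
\frac{\sqrt{\sum_i (D_i - \mathrm{MD})^2}}{\sqrt{\sum_i D_i^2}}, \qquad
D_\parallel/D_\perp = \frac{D_1}{(D_2+D_3)/2}.$$

Noisy fits can produce negative eigenvalues. We clamp them at zero *for the
indices only* (keeping FA in $[0,1]$ and MD consistent with the clamped
triple), keep the raw values in the eigen system for diagnostics, and count
clamped voxels in the pipeline report. Eigenvectors are sign-normalised so
the largest-magnitude component is positive, making outputs deterministic;
ties between degenerate eigenvalues keep LAPACK's stable ordering.

## The gradient scheme

The emulated acquisition uses 19 diffusion directions at
$b = 1150\ \mathrm{s/mm^2}$ plus one $b=0$ volume. The direction set is not
published, so the package ships a fixed 19-direction table generated once by
seeded electrostatic-repulsion minimisation on the sphere
(`repulsion_directions()`, antipodally symmetric energy); it is committed as
an FSL bval/bvec pair so results are reproducible without pretending to be
the original table. Any user scheme is accepted if it has a $b=0$
measurement, at least six non-coplanar directions, and a (b-normalised)
design condition number below 100.

Two sequence-level checks motivate the acquisition: the two-point rule
$b_{\mathrm{opt}} = 1.1/D$ puts the optimum near
$1150\ \mathrm{s/mm^2}$ for fascicular diffusivities around
$0.96 \times 10^{-9}\,\mathrm{m^2/s}$, and the Stejskal–Tanner closed form
$b = (\gamma G_0 \delta)^2 (\Delta - \delta/3)$ evaluates to
$\approx 1.13 \times 10^3\ \mathrm{s/mm^2}$ for the nominal sequence
parameters ($\delta = 3$ ms, $\Delta = 27$ ms, $G_0 = 0.26$ T/m) — slightly
below the nominal 1150, the difference attributable to imaging-gradient
contributions not in the closed form.

## The synthetic nerve phantom

`phantom_spec()` describes the study conditions at desk scale, and its
defaults *are* those conditions:

| parameter | default | rationale |
|---|---|---|
| grid | 128 × 64 × 16 | half the acquired 256 × 128 in-plane matrix |
| voxel size | 0.07 × 0.07 × 0.625 mm | 70 µm in-plane (acquired: 35 µm), 16 slices of 0.625 mm |
| nerve radius | 2.2 mm | nerve CSA ≈ 15 mm², within the observed spread; see below |
| fascicles | 8 | observed ≈ 8 per slice |
| fascicular-ratio target | 0.46 | observed FR 0.46 ± 0.07 |
| perineurium ring | 0.07 mm | two voxels at the acquired 35 µm resolution |
| drift amplitude | 0.08 mm (capped) | fascicular pattern changes over sub-millimetre distances |
| compartment tensors | fascicle (0.81, 0.41, 0.37); perineurium (1.07, 0.75, 0.53); epineurium (0.03, 0.03, 0.03) ×10⁻⁹ m²/s | the study's per-compartment means |
| S0 | fascicle 100, perineurium 160, epineurium 130; background 0 | T2 contrast ordering: hyperintense perineurium, hypointense fascicles, signal-free perfluorocarbon bath |
| noise σ | S0(fascicle)/14 | calibrates b = 0 fascicular SNR to ≈ 14 |

Three geometric decisions deserve their reasoning spelled out:

* **Nerve radius 2.2 mm.** The mean observed nerve CSA (12.3 mm²,
  radius ≈ 1.98 mm) cannot hold eight fascicles at FR 0.46 *and* disjoint
  perineurium rings: the implied effective packing fraction exceeds the
  optimal packing of eight disks in a circle. At radius 2.2 mm
  (CSA ≈ 15.2 mm², well within the 12.34 ± 3.53 mm² spread) the ring-padded
  packing fraction drops to ≈ 0.59, attainable in practice.
* **Placement algorithm.** Fascicle disks are placed by best-candidate dart
  throwing (each disk takes the candidate position with the largest
  clearance) followed by a deterministic overlap-relaxation pass that
  pushes intersecting pairs apart and re-projects into the nerve. Pure
  rejection sampling jams well below the required density; the relaxation
  pass reaches it while remaining fully seeded and deterministic. If the
  requested parameters are genuinely infeasible the generator fails with an
  error naming them rather than silently degrading the geometry.
* **Drift capping.** Each fascicle's sinusoidal in-plane drift (random
  phase and direction per fascicle, one period over the segment) is capped
  at half its clearance to neighbours and its full clearance to the nerve
  boundary, so compartments stay pairwise disjoint on *every* slice — the
  partition property `fascicles + perineurium + epineurium = nerve` holds
  exactly in voxel counts and the tests assert it. In a tightly packed
  nerve many caps come out near zero; drift is therefore most visible in
  sparser configurations.

Fascicle and perineurium tensors are oriented along the local fascicle
tangent (slice axis plus drift derivative); perineurium ring voxels inherit
the tangent of their nearest fascicle. Noise is Rician,
$|S + n_1 + i n_2|$ with $n_1, n_2 \sim N(0, \sigma^2)$ — the standard
magnitude-image model, the only noise fact stated about the acquisition
being its SNR. `estimate_snr()` recovers σ from the background (Rayleigh)
standard deviation with the $\sqrt{2 - \pi/2}$ correction.

**What the phantom does not emulate:** k-space/EPI artifacts, T2 decay,
partial-volume mixing at the acquired 35 µm scale (the ring is resolvable
on purpose; a 1-voxel ring serves as a partial-volume stress case),
fascicle splitting/merging, and — importantly — real per-fascicle
heterogeneity: all fascicles share one ground-truth tensor, so
between-fascicle index variance in the phantom reflects only discretisation
and noise. Passing tests therefore validate the *machinery* (estimators,
statistics, geometry handling), not biological variability; study-level
quantities that depend on the cadaveric images (their ICC of 0.98, CoV of
0.17, pooled r of 0.74) are deliberately not reproduction targets.

## Morphometry

Areas are voxel counts times in-plane voxel area — matching how common
image tools measure manually traced regions — with no sub-voxel polygon
estimation. Ratios always use nerve CSA as the denominator (never the sum
of compartment areas), because real manual segmentations may leave
intra-nerve voxels unlabelled. Slice exclusion is an explicit include-list,
not an automatic detector, since the quality control it models was visual.

## Statistics

The statistical toolbox mirrors the study design:

* `coefficient_of_variation()` and `cov_within_between()` separate FA
  variability along a fascicle from variability between fascicles on a
  slice.
* `icc_oneway()` implements ICC(1) from one-way random-effects ANOVA mean
  squares, the single-rater form by default (the averaged-ratings ICC(1,k)
  behind a flag), unclipped so negative estimates remain visible. The tests
  verify it against `stats::aov` mean squares to $10^{-10}$ and the exact
  $-1/(k-1)$ value for tables with identical subject means.
* `slice_trend()` regresses an index on slice position (slope, Pearson r,
  two-sided slope test). A constant series returns slope 0, r 0, p 1 by
  convention rather than erroring, because a flat profile is a legitimate
  finding.
* `fascicle_correlation_test()` fits an OLS slope per nerve sample and
  tests the slopes against zero with a one-sample t-test, reporting a
  pooled Pearson r alongside (the study reports r for some comparisons and
  p only for others; pooling is the adopted reading). Zero-variance slopes
  report p = 0 (below machine tolerance) or p = 1 at zero mean. Its type-I
  error is verified by simulation (1000 null replicates) to be 0.05 ± 0.02.
* `compartment_contrast()` computes per-slice percent differences and
  their mean ± SD, the form in which cross-compartment MD/FA differences
  are quoted.

No multiple-testing correction is applied (none was in the emulated
analysis); the pipeline report counts the tests it ran. Shapiro–Wilk,
two-way ANOVA and Tukey post-hocs are deliberately out of scope — the
exported per-group tables feed any standard stats package.

## Tractography and displays

`track_streamlines()` integrates the principal-eigenvector field by Euler
steps, bidirectionally from each seed, with nearest-neighbour field lookup
(the phantom's fields are piecewise constant; trilinear interpolation would
blur compartment boundaries). The eigenvector sign is re-aligned with the
previous step at every step, making the tracker invariant to global sign
flips — e1 is a line field, not a vector field. Termination: FA below
`fa_min`, turning angle above `angle_max`, volume exit, or `max_steps`.
The defaults — step = half the smallest voxel edge, `fa_min` 0.15,
`angle_max` 60°, seeds on every fascicle voxel of the middle slice — are
conventional deterministic-tractography settings; none are stated in the
emulated study, so all are configurable. Streamlines export to TrackVis
TRK (a minimal v2 writer/reader pair, since no installed R package writes
TRK); ellipsoid glyphs (eigenvalue-proportional semi-axes, eigenvector
orientation, |e1| RGB colouring: red x, green y, blue z) export as TSV for
any renderer. On noisy voxelwise fits a fraction of tracks jitter out of
their fascicle; on the ground-truth or noiseless field they follow
fascicles over the full segment, and the containment audit
(`streamline_label_audit()`) quantifies both.

## Numerical choices and degenerate inputs

* Non-positive signals (possible under heavy noise) are floored at
  $10^{-3}$ times the smallest positive signal before the log, with a
  warning and a per-fit count; all-zero vectors are an error.
* $D_\parallel/D_\perp$ with $D_2 + D_3 = 0$ is an error ("degenerate
  radial diffusivity"), not an infinity.
* An all-zero eigenvalue triple has FA defined as 0.
* Scheme validation rejects: no $b=0$, fewer than six directions, coplanar
  direction sets (rank < 7), non-unit directions, condition number ≥ 100.
* All randomness (phantom geometry, noise, direction generation) flows
  from explicit integer seeds; geometry and noise use separate streams so
  the same anatomy can be re-noised.

## Problem sizes

The package's own working scale is the desk-scale default grid
(128 × 64 × 16 at 70 µm in-plane); the full acquired scale (256 × 128 × 16
at 35 µm) is one `phantom_spec(grid = c(256, 128, 16),
voxel_size = c(0.035, 0.035, 0.625))` away. The test suite mostly uses a
further-reduced 64 × 32 × 8 grid at 140 µm, which preserves every geometric
proportion and all compartment physics; noise-robustness checks run 20
seeds at the default scale, and the type-I-error simulation uses 1000
replicates.

## Known limitations

* The phantom's fascicles are circular cylinders with sinusoidal drift; no
  splitting, merging, or non-circular cross-sections.
* A single ground-truth tensor per compartment: optional per-voxel jitter
  is not enabled by default, so agreement statistics on phantom data
  overstate what real inter-fascicle variability would give.
* The region-averaged estimator assumes compartment homogeneity; with
  drifting fascicles the tangent varies slightly along z, which perturbs
  region fits at the $10^{-3}$ level — visible only in the noiseless
  round-trip, which therefore uses the straight-extrusion configuration.
* Nearest-neighbour tracking on noisy voxelwise fields underestimates
  containment relative to smoother interpolation schemes.
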
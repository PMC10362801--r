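---
title: "Dual-ratio DiFC: model, noise, and calibration methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-ratio DiFC: model, noise, and calibration methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drdifc)
```

## The measurement problem

Diffuse in vivo flow cytometry (DiFC) detects transient fluorescence peaks
from labeled cells flowing through blood vessels a few millimeters below
the tissue surface. Each transit produces a small bump in the photodetector
current on top of a large, noisy background dominated by tissue
autofluorescence (AF). The depth at which cells remain detectable is set by
the signal-to-noise ratio (SNR) of that bump, and the dual-ratio (DR)
measurement — a self-calibrating combination of four source–detector
intensities — is a candidate for pushing that depth limit, because it
cancels multiplicative per-optode noise exactly and de-weights superficial
tissue where AF concentrates.

`drdifc` implements the complete forward model and the calibration
procedures needed to study this question in simulation: photon-transport
Green's functions, the fluorescence Jacobian, the SD/SR/DR measurement
algebra, a coupling-coefficient noise model, robust trace calibration, and
the derived analyses (SNR maps, transit traces, depth scans, and
non-cancelable-noise sweeps).

## Forward model

### Transport Green's functions

The medium is a homogeneous voxelized slab (`optical_medium()`) with
absorption `mu_a` (default 0.002 mm⁻¹), scattering `mu_s` (7 mm⁻¹),
Henyey–Greenstein anisotropy `g` (0.9), and refractive index 1.37 against
air, representative of tissue at 810 nm. `run_photon_mc()` launches photons
from a surface optode and scores the continuous-wave fluence-rate Green's
function Φ (fluence per unit source power, mm⁻²) in every voxel. Sources
are pencil beams at normal incidence; detectors are modeled by the adjoint
method as cone beams whose directions fill the fiber acceptance cone
(numerical aperture defined in the exterior medium, the fiber convention),
refracted into the tissue. This asymmetry is not cosmetic: at millimeter
length scales the light is not fully diffuse, and the pencil/cone
distinction is what produces the asymmetric double-peaked transit shapes
discussed below.

Numerical conventions, chosen once and fixed:

* **Scoring.** Collision estimator: each collision of weight `w` adds
  `w/(mu_t V)` to its voxel, algebraically equal to absorbed-weight
  deposition divided by `mu_a` per voxel volume and still defined as
  `mu_a -> 0`.
* **Boundaries.** Fresnel reflection/refraction (unpolarized, with total
  internal reflection) at the `z = 0` face; the other five faces terminate
  photons and tally their weight. The launch weight is reduced by the
  specular Fresnel loss, so Green's functions are per unit power incident
  on the surface.
* **Time gates.** Histories are binned by optical path length into `n`
  gates ending at `t_end_ns` (default 10 gates to 10 ns); gated maps store
  per-unit-time fluence so the CW map is `sum(value * dt)`
  (`cw_integrate()`). Histories outliving the last gate are censored and
  tallied.
* **Termination.** Russian roulette below weight 1e-4 with survival factor
  10. The tallies balance launched weight exactly (to round-off), which the
  test suite asserts.
* **Reproducibility.** The kernel uses its own deterministic
  xoshiro256**-based generator; a fixed seed gives a bit-identical grid and
  leaves the caller's R RNG stream untouched.

`diffusion_green()` provides the semi-infinite extrapolated-boundary
closed form (pencil beam as a buried isotropic source at one transport
mean free path, mirrored in the extrapolated boundary). It serves as a fast
fallback (`diffusion_fluence_grid()`, `engine = "diffusion"` in
`build_w_set()`) and as the independent oracle for the kernel. The two
agree within a few percent in the 2–6 mm range at the reference optical
properties; within ~1 transport mean free path of the beam, diffusion
theory overestimates badly (tens of percent), and at large distances the
finite box's absorbing faces make the semi-infinite formula a systematic
upper bound — both regimes are characterized in the tests rather than
hidden.

### Fluorescence Jacobian and reflectance

For a source–detector pair, the sensitivity of the detected fluorescence
to a fluorophore in voxel `r` is the fluorescence Jacobian

> W(r) = Φ_src(r) · Φ_det(r) · V   (mm⁻¹),

(`sensitivity_map()`), with Φ_det computed by reciprocity from the
detector-side adjoint simulation. Excitation and emission optical
properties are taken equal. The measured reflectance then decomposes into
a distributed AF background plus a point-target term:

> R = P_src · Σᵢ W(rᵢ) · μa_AF(rᵢ)·η_AF(rᵢ) + P_src · W(r_t) · μa_t·η_t,

implemented as `background_reflectance()` and `target_reflectance()`
(`total_reflectance()` reports both components). The AF profile
(`af_model()`) is either homogeneous or surface-weighted — an exponential
that halves every `half_depth` (default 0.1 mm), evaluated at voxel-center
depths (first layer at `voxel/2`). Targets map to their nearest voxel by
default, matching the voxelized transport; trilinear interpolation is
available for smooth transit rendering. Default coefficients are the
phantom-calibrated values: 228e-9 mm⁻¹ (surface-weighted prefactor),
6.81e-9 mm⁻¹ (homogeneous), and 43.3e-6 mm⁻¹ for the target.

### Measurement types

With two sources (1, 2) and two detectors (A, B) arranged symmetrically
(defaults: detectors at ∓3.5 mm, sources at ∓0.5 mm, giving 3 mm and 4 mm
separations), the package computes single-distance changes
(`delta_sd()`), single ratios (`single_ratio()`), and the dual ratio

> DR = sqrt( (I_A2 · I_B1) / (I_A1 · I_B2) ),

the geometric mean of two single ratios in which every per-optode
multiplicative factor appears once in a numerator and once in a
denominator and cancels exactly (`dual_ratio()`).
`validate_dr_layout()` checks the geometric requirement — the optodes
forming the short distance of one ratio must form the long distance of the
other — with a 1e-6 mm tolerance suited to exact simulated layouts
(configurable for measured geometry).

### Coupling-coefficient noise

Measured intensities are reflectances multiplied by Gaussian
coupling-coefficient random variables of mean one: one factor per optode
with variance `p_opt · sigma_rel²`, shared by both pairs containing that
optode within a draw, and one non-cancelable (NC) factor per pair with
variance `p_nc · sigma_rel²`, constrained by `2 p_opt + p_nc = 1`
(enforced at construction). Under this construction every single-distance
intensity has relative noise `sigma_rel` regardless of `p_nc`, while the
DR retains only the NC part: to first order its relative noise is
`sqrt(p_nc) · sigma_rel`. Both facts are verified by sampling in the test
suite. Defaults are `sigma_rel = 0.031` and `p_nc = 0.05`, the calibrated
operating point. Factors are drawn untruncated in a documented fixed order
(C1, C2, CA, CB, then the four NC factors); at `sigma_rel ≈ 0.03` a
negative draw has probability ~1e-200, and the analytic baseline-noise
path refuses `sigma_rel > 0.2` where the small-noise approximation would
degrade.

**SNR definition.** The literature this package models uses SNR throughout
without printing its formula; the package's documented convention is the
expected background-subtracted change of a data type divided by the
baseline-condition standard deviation of the same data type, sign
retained (a DR excursion below −1 is as detectable as one above +1). The
baseline standard deviation is `sigma_rel · R0` analytically for SD pairs;
for DR it is estimated by coupling-draw sampling (default 1e4 draws, the
reference) or by the delta-method closed form `sqrt(p_nc)·sigma_rel·DR0` —
the two agree to a few tenths of a percent at the default noise level, and
the closed form is used where many repeated scans make sampling wasteful
(e.g. `pnc_sweep()` grids).

## Calibration from traces

`calibrate_trace()` implements the trace-side procedures on 2 kHz detector
currents:

* **Background**: samples more than 3 scaled median absolute deviations
  from the trace median are masked; the centered 1 s moving mean is taken
  with windows truncated at the ends; the median of moving means is the
  background. **Noise**: identical with the moving standard deviation.
  The alternative display-style subtraction (5 s moving median,
  `subtract_moving_median()`) and longer noise windows are available as
  options; calibration defaults to the 1 s procedure.
* **Peaks** (`detect_peaks()`): local maxima of the background-subtracted
  raw trace at least five noise standard deviations high and at least 1 s
  apart (the larger of two close candidates wins). The raw (unsmoothed)
  trace is used — smoothing before peak search is a defensible alternative
  but changes amplitude statistics, so the package takes the simpler
  convention and documents it.
* **Units**: currents convert to reflectance via a fixed constant
  (271e-15 W mm⁻² nA⁻¹ by default, from detector gain 1e4, area
  0.565 mm², 810 nm). It cancels from every unitless quantity (SNR,
  `sigma_rel`); only the fitted coefficients feel it.
* **Coefficient fits**: `fit_af_het()`, `fit_af_hom()`, and
  `fit_target()` are the exact algebraic inverses of the forward
  background/target model given a Jacobian grid — forward-evaluating a
  fitted coefficient reproduces the input reflectance to machine
  precision, which the tests assert. The target fit assumes the peak
  maximum occurred at the highest-sensitivity voxel.

## Synthetic data

`make_trace()` generates traces as `background × (1 + N(0, sigma_rel))`
per sample plus scheduled transient peaks (Gaussian with a given FWHM, or
an arbitrary transit waveform, e.g. rendered from `flow_trace()` via
`flow_trace_waveform()`). Two points deserve emphasis. First, the noise is
*multiplicative relative*, matching the constant-relative-noise model
`sigma_I = sigma_rel · R`; additive-absolute noise is a different (and
also common) photodetector convention and is deliberately not what this
generator produces. Second, the generator embeds every parameter in a
`ground_truth` attribute so tests never re-derive truth from the data.

What the generator does *not* emulate: detector drift, dark current, shot
noise (Poisson statistics), correlated noise between optodes beyond the NC
term, and fluorophore photophysics (saturation, bleaching, lifetime).
Passing calibration-recovery tests on these traces therefore demonstrates
the estimators' correctness under the stated noise model, not robustness
to every artifact of real hardware.

`make_toy_grids()` builds ≤ 32³ fluence/Jacobian fixtures with closed-form
structure (uniform, single-voxel, separable) so that every reflectance sum
in the package can be checked against hand-computable values and explicit
per-voxel loops.

## Derived analyses

`build_w_set()` runs one transport simulation per optode and forms the
four pair Jacobians. `snr_map()` evaluates the SNR for a target at every
voxel of the central y-layer; `flow_trace()` scans it along a parallel
(x) or perpendicular (y) transit path, with the time axis given by the
target velocity (default 25 mm/s; the 17 mm/s phantom pump speed is a
config alternative); `depth_scan()` follows the SNR below each data
type's optode centroid downward and locates the deepest `|SNR| = 1`
crossing by linear interpolation between the bracketing grid depths
(reported as censored if `|SNR| > 1` persists to the bottom of the grid);
`pnc_sweep()` repeats the scan over a grid of `p_nc` values with common
random numbers and reports the largest value at which the DR still
out-depths the deepest SD pair. For the DR scan the centroid is the mean
x of all four optodes (recorded in the output); for SD pairs it is the
midpoint of the two participating optodes.

Three signatures of the model are worth knowing when reading outputs:

* A parallel SD transit at shallow depth is a **doublet** — one lobe as
  the target passes under the detector, one under the source — with the
  source-side lobe higher because the pencil beam drives light deeper than
  the cone collects it. Swapping the beam models flips the asymmetry.
* A parallel DR transit is **triphasic**: the DR drops below baseline as
  the target passes under the first detector, rises above it under the
  sources, and drops again under the second detector.
* Whether DR out-depths SD depends on the AF distribution: with
  surface-weighted AF the DR's de-weighting of superficial voxels
  suppresses background noise more than signal and it sees deepest; with
  homogeneous AF the advantage largely disappears.

## Problem sizes and what desk-scale results mean

The reference configuration (`default_config()`) is a 30 mm cube at
0.1 mm voxels with 1e9 photons per optode — the fidelity at which the
study this package models was run, and feasible here only with patience.
The package's own tests and acceptance script use desk-scale conditions
chosen once: a 16 × 10 × 8 mm box at 0.25 mm voxels with 1e6–2e6 photons
per optode for the derived analyses, and a 30 × 30 × 20 mm box at 0.2 mm
voxels with 1e7 photons for the transport-versus-diffusion check. At desk
scale the *orderings and shapes* above are stable, but absolute maximum
depths and pNC crossovers are photon-budget- and box-size-dependent: a
smaller box truncates the AF background sum, lowering baseline noise and
inflating depths (the desk-scale scans reach ~6 mm where the full-scale
analysis reports 3–4 mm). Depth tables therefore record the photon budget
and seed alongside their values, and only orderings are asserted in tests.

## Known limitations

* Homogeneous optical properties only; no heterogeneous tissue, no
  distinct excitation/emission wavelengths.
* The adjoint cone-beam representation of the detector is an
  approximation whose accuracy is only probed qualitatively (through the
  transit-shape signatures), not independently verified.
* The five non-surface faces are absorbing; simulated volumes must be
  large enough that this truncation is acceptable for the quantity of
  interest (see the depth-inflation note above).
* Grid persistence uses R serialization rather than a cross-language
  hierarchical format; use the CSV/JSON exports for interchange.
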
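# drdifc

Simulation and calibration tools for **dual-ratio diffuse in vivo flow
cytometry (DiFC)**.

DiFC detects fluorescently labeled cells circulating in blood vessels a few
millimeters deep by shining laser light on the tissue surface and watching
for transient fluorescence peaks in the diffusely collected signal. The
detection depth is limited by noise riding on a large tissue
autofluorescence (AF) background. The **dual ratio (DR)** is a
self-calibrating measurement built from two sources (1, 2) and two
detectors (A, B) in a symmetric line:

```
DR = sqrt( (I_A2 · I_B1) / (I_A1 · I_B2) )
```

Every multiplicative factor attached to a single optode — coupling, gain,
source power — appears once in the numerator and once in the denominator
and cancels exactly; only "non-cancelable" (NC) noise, a fraction `p_NC`
of the intensity variance not attributable to per-optode factors,
survives. The DR also de-weights superficial tissue, so when AF
contributors are concentrated in the skin it can out-perform conventional
single-distance (SD) measurements at depth.

`drdifc` provides everything needed to study this quantitatively:

* a voxel **Monte-Carlo photon transport kernel** (Rcpp; Henyey–Greenstein
  scattering, Fresnel surface, pencil and NA-cone beams, time gating,
  exact weight accounting, bit-reproducible seeding) plus a semi-infinite
  **diffusion-theory closed form** used as fast fallback and independent
  oracle;
* the **fluorescence Jacobian** `W = Φ_src · Φ_det · V` and the
  reflectance model `R = P_src (Σ W·μaAF·ηAF + W(r_t)·μa_t·η_t)` for
  distributed AF (homogeneous or exponentially surface-weighted) plus a
  point target;
* the **SD/SR/DR measurement algebra** with layout-symmetry validation;
* a **coupling-coefficient noise model** (Gaussian per-optode and NC
  factors, `2 p_opt + p_NC = 1`) with sampled and delta-method DR noise;
* robust **trace calibration**: outlier-masked moving-window background
  and noise estimates, threshold-and-separation peak detection,
  current-to-reflectance conversion, and exact-inverse fits of the AF and
  target fluorescence coefficients;
* the derived **analyses**: SNR maps over target position, simulated
  transit traces, maximum-measurable-depth scans, and `p_NC` sweeps;
* a **synthetic trace/grid generator** with embedded ground truth, a YAML
  configuration layer, and a `run_pipeline()` workflow driver (thin CLI in
  `inst/cli/difc`).

## Worked example

```r
library(drdifc)

## Dual-ratio noise cancellation on a reflectance quartet (pW mm^-2)
r0 <- intensity_quartet(A1 = 46.1, A2 = 30.2, B1 = 30.5, B2 = 46.3)
dr_noise_stats(r0, noise_params(sigma_rel = 0.031, p_nc = 0),    1e5, seed = 1)$sd
#> [1] 7.297251e-17        # per-optode noise cancels to machine precision
dr_noise_stats(r0, noise_params(sigma_rel = 0.031, p_nc = 0.05), 1e5, seed = 1)$sd
#> [1] 0.004558015         # 5% NC noise survives ...
sqrt(0.05) * 0.031 * dual_ratio(r0)
#> [1] 0.004553645         # ... at the predicted sqrt(p_NC)·sigma_rel level

## Calibrate a synthetic 60 s, 2 kHz detector trace with known truth
sched <- peak_schedule(times_s = seq(3, 57, length.out = 20),
                       amplitudes_nA = rep(47.3, 20), widths_ms = 10)
tr <- make_trace(background = 170, sigma_rel = 0.031, sched, seed = 11)
calibrate_trace(tr)
#> <calibration_result>
#>   background 170 nA (46.08 pW mm^-2)
#>   noise      5.203 nA (1.41 pW mm^-2), sigma_rel 0.0306
#>   peaks      20 detected, mean amplitude 53.42 nA

## Desk-scale Monte-Carlo sensitivity set and a depth scan (~1 min)
med <- optical_medium(extent = c(16, 10, 8), voxel = 0.25)
ws <- build_w_set(med, measurement_geometry(), n_photons = 1e6, seed = 3)
depth_scan(ws, af_model("surface_weighted"), target_coeff = 43.3e-6,
           noise_params(0.031, 0.05), dr_sd_method = "delta")
#> <depth_scan> surface_weighted AF, p_nc 0.05
#>  data_type centroid_x_mm max_depth_mm censored
#>         A1          -2.0     5.873658    FALSE
#>         A2          -1.5     6.069894    FALSE
#>         dr           0.0     6.356470    FALSE
```

The calibration recovers the generator's 170 nA background to 0.03% and
its 3.1% relative noise to ~1%, finds all 20 scheduled transits, and
converts currents to reflectance with the default 271e-15 W mm⁻² nA⁻¹
detector constant. The depth scan shows the headline qualitative result:
with surface-weighted AF the dual ratio keeps `|SNR| > 1` deeper
(6.36 mm) than either single-distance pair — with the caveat that
absolute desk-scale depths depend on the photon budget and simulated
volume (see the methods vignette, `vignettes/dual-ratio-difc.Rmd`).

A parallel flow transit evaluated with `flow_trace()` shows the model's
signature shapes: SD pairs produce a doublet whose source-side lobe is
higher (pencil source vs cone detector), and the DR is triphasic —
below baseline under one detector (SNR −8.6 in the run above), above it
under the sources (+35.8), below again under the other detector (−4.6).

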
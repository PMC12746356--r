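# coroflow

Simulation and quantification of 3D phase-contrast (PC) coronary flow MRI,
at desk scale.

Measuring blood velocity in the proximal coronary arteries with MRI is hard:
the vessels are 2–4.5 mm wide (2–4 voxels at 1.2 mm isotropic resolution),
they move with every heartbeat and breath, and flow is slow. One practical
acquisition strategy encodes the three velocity components in four separate
consecutive scans (reference, through-plane, right–left, foot–head), so that
motion *between* scans becomes a rigid offset that image registration can
undo. `coroflow` provides a complete, testable analogue of that measurement
for people developing or validating PC post-processing: a digital flow
phantom with known ground truth, a four-point acquisition simulator, and the
full analysis chain.

The phase model is the standard four-point system, per voxel

    phi_k = (pi / VENC) * m_k . v + phi_0,    k = 1..4

with VENC = 50 cm/s and encoding matrices of rank 3 ("balanced"
Hadamard-like rows ±(1,1,1)/2 or "referenced" unit rows). The chain:

* `build_phantom()` — spline-centerline vessels, parabolic Poiseuille flow
  v(ρ) = v_c (1 − (ρ/R)²), flux-conserving stenoses (lumen R√(1−α),
  centerline speed v_c/(1−α)), analytic truth curves.
* `encode_study()` / `make_mask()` — flow-encoding phase, k-space rigid
  translations, complex Gaussian noise, center-weighted pseudo-random
  undersampling (nominal factor 14).
* `zero_fill()` / `cs_reconstruct()` — zero-filled and compressed-sensing
  reconstruction (ISTA, data consistency + orthogonal Daubechies-4 wavelet
  l1 penalty, provably monotone objective).
* `canny3d()`, `estimate_translation()`, `apply_correction()` — 3D edge
  contours, translational co-registration with sub-voxel refinement,
  correction of magnitude and phase plus magnitude averaging.
* `decode_velocity()`, `fit_background()`, `displacement_correct()` —
  least-squares four-point decoding, quadratic background-phase removal,
  single-step flow-displacement relocation (d = v·Δt per axis).
* `build_centerline()`, `segment_vessel()`, `extract_curve()`,
  `prune_ostium()` — 100 perpendicular slices along a marker spline,
  masked per-slice maximum speed, and the ostium pruning rule
  (v_{n+i} ≤ v_mean + σ for i = 0,1,2, reference window 10–25 mm).
* `bland_altman()`, `paired_ttest()`, `scan_rescan_report()`,
  `align_ffr()`, `render_mip()` — agreement statistics, FFR-trace arc
  alignment, maximum-intensity projections.
* `run_pipeline()` / `make_fixtures()` — end-to-end orchestration and the
  four canonical test studies. A thin command-line wrapper lives in
  `inst/scripts/coroflow-pipeline.R`.

Studies round-trip to NIfTI (magnitude + phase pairs) with a JSON sidecar
via `write_study()` / `read_study()`, so externally acquired volumes can
enter the chain.

## Worked example: localizing a 50% stenosis

```r
library(coroflow)

ph <- build_phantom(stenosed_tube_spec(peak_speed = 10, severity = 0.5),
                    c(48, 48, 48))
ph
#> <digital_phantom> 48x48x48 voxels, 1 vessel(s): tube; peak true speed 20.00 cm/s

study <- encode_study(ph, noise_snr = 30, seed = 1)
field <- displacement_correct(decode_velocity(study), study$params)
field
#> <velocity_field> 48x48x48, peak speed 80.26 cm/s [wrap flagged]
```

The whole-volume peak of 80 cm/s and the wrap flag come from *background*
voxels, whose magnitude is essentially zero and whose phase — hence decoded
velocity — is random; this is normal for PC data and is why quantification
is always mask-restricted:

```r
path  <- build_centerline(ph$vessels[[1]]$control_points, n_slices = 100)
mask  <- segment_vessel(field$magnitude, path, radius_mm = 2.5,
                        threshold_frac = 0.5)
curve <- prune_ostium(extract_curve(field, path, mask))
curve
#> <velocity_curve> 100 slices over 45.6 mm; proximal (<=25 mm) peak 17.47, average 10.59 cm/s

summary(curve)
#>     peak  average
#> 17.46520 10.58549
curve$arc[which.max(curve$vmax)]
#> [1] 21.64848
```

The measured curve peaks at arc 21.6 mm — within 1.2 mm of the true
stenosis center at 22.8 mm — and the proximal peak of 17.5 cm/s against a
10 cm/s base (ratio 1.75) reflects the true 2.0× stenotic speed-up minus
partial-volume underestimation of the narrowed 1.4 mm-radius jet at 1.2 mm
voxels. The analytic truth from `sample_truth_curve(ph, "tube")` gives
(peak 19.8, average 11.3) for comparison.

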
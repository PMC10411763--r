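# voxdose

Voxel-based internal dosimetry for serial SPECT/CT studies, with automated
rigid co-registration — an R toolkit covering the whole chain from
reconstructed count volumes to an absorbed-dose map and per-organ dose
report, validated end to end on synthetic digital phantoms with exact
ground truth.

## Who this is for

Medical-physics and nuclear-medicine researchers who need a transparent,
tested implementation of voxel-level MIRD dosimetry building blocks:

* **Rigid intramodality co-registration** of SPECT volumes by minimization
  of the mean squared intensity error (6 degrees of freedom, quasi-Newton
  descent with numerical gradients; gradient tolerance 1e-4, convergence
  tolerance 1e-5, at most 100 iterations), with an optional smoothed
  normalized-cross-correlation cost for comparison.
* **Registration quality and phantom QC**: %RMSE (RMS voxel count
  difference relative to total counts), IAEA/NEMA-style integral
  uniformity, cold-sphere contrast, and rod-profile resolution by
  multi-Gaussian fitting (FWHM = 2&radic;(2 ln 2)&thinsp;&sigma;).
* **Per-voxel time-integrated activity**: trapezoidal uptake from injection
  to the per-voxel peak plus the analytic tail of a bounded
  double-exponential fit, A&#8321;e^(&minus;&lambda;&#8321;u) +
  A&#8322;e^(&minus;&lambda;&#8322;u), with explicit mono-exponential and
  physical-decay fallbacks.
* **Dose-point-kernel convolution**: dose(v) = &Sigma;&#8347;
  TIA(s)&middot;K(v&minus;s), FFT with zero padding, medium-specific voxel
  S-value kernels selected by a 300-HU bone segmentation, and a
  volume-of-interest report at 40% of the organ maximum dose.
* **Quantitation-preserving I/O**: DICOM series and NIfTI-1 with rescale
  slopes honoured both ways — total counts survive format round trips to
  0.1%, the failure mode that famously corrupts converted SPECT counts.
* **Synthetic ground truth**: a Jaszczak-style digital phantom (uniform
  740 MBq compartment, cold spheres and rod sectors, optional fiducial)
  under known rigid motion, and a four-time-point patient-like study with
  known double-exponential kinetics, closed-form TIA and a brute-force dose
  reference.

The shipped S-value kernels are analytic toys (their provenance field says
so); drop in real Monte-Carlo tables via the JSON kernel format for
anything beyond software validation.

## Worked example

Simulate the 18-study phantom rotation experiment (0/5/10 degrees about the
bed axis, three replicates, with and without a fiducial marker), register
every study to its 0-degree reference, and summarize:

```r
library(voxdose)

spec <- phantom_spec()            # 740 MBq in 6.1 L, 128^3 at 4 mm
rep <- run_phantom_experiment(spec, seed = 20, qc = FALSE)
subset(rep$per_study, angle_deg == 5 & fiducial,
       c(study_id, rotation_error_deg, translation_error_mm,
         percent_rmse_before, percent_rmse_after))
```

```
                  study_id rotation_error_deg translation_error_mm percent_rmse_before percent_rmse_after
4 rot05_with_fiducial_rep1             0.2609              0.06215           2.067e-05          1.451e-05
5 rot05_with_fiducial_rep2             0.2528              0.05700           2.066e-05          1.448e-05
6 rot05_with_fiducial_rep3             0.2691              0.05525           2.066e-05          1.445e-05
```

The 5-degree rotation is recovered to ~0.26 degree and 0.06 mm (well inside
half a 4 mm voxel), and %RMSE drops by about 30% after reslicing to the
reference — at 6e7 total counts, the residual %RMSE is dominated by Poisson
noise between the two acquisitions. Across all 18 studies the recovery rate
at 0.5 degree / half a voxel is 18/18. The patient-like chain runs the same
way:

```r
ps  <- make_patient_series()                       # 1.5/5/24/240 h series
tia <- tia_map(ps$series, ps$calibration, half_life_h = 159.5)
kernels <- list(soft_tissue = generate_toy_kernel("Lu177", 4),
                bone        = generate_toy_kernel("Lu177", 4, medium = "bone"))
dose <- convolve_dose(tia, kernels, segment_bone(ps$ct))
voi_by_cutoff(dose, c(-45, 20, -10))               # left kidney seed point
#> <voi_stats> 364 voxels (23.30 mL) at >= 40% of max: mean 1718 mGy, max 2460 mGy
```

The mean kidney dose agrees with the analytic brute-force reference for
this synthetic patient to well under 1% (noiseless) and a few percent under
Poisson noise.

A thin command-line interface over the same functions is installed at
`inst/cli/voxdose.R` (verbs: `simulate-phantom`, `coreg`, `qc`, `tia`,
`dose`, `voi`, `compare`, `phantom-experiment`).

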
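---
title: "voxdose: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{voxdose: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

voxdose is a toolkit for voxel-level internal dosimetry on serial SPECT/CT
studies: it co-registers the SPECT volumes of a multi-time-point study,
integrates each voxel's time-activity curve, and convolves the resulting
time-integrated-activity (TIA) map with voxel S-value kernels into an
absorbed-dose map with volume-of-interest (VOI) reporting. Because no public
phantom or patient acquisitions accompany this class of software, the package
also ships a synthetic-data generator with exact ground truth — known rigid
motion, known kinetics, closed-form TIA and a brute-force dose reference —
so that every stage of the chain is testable end to end. This vignette
records the models, the tunable parameters, and the design decisions that
were genuinely open.

## Coordinate conventions

A `volume3d` is a 3-D scalar grid with voxel spacing (mm), the world
position of the centre of voxel `(0,0,0)`, orthonormal direction cosines and
a value kind (`counts`, `HU`, `activity_MBq`, `tia_MBq_s`, `dose_mGy`).
Indices are 0-based and voxels are node-centred:
`world = origin + orientation %*% (spacing * index)`. The world frame is the
scanner frame in the DICOM (LPS) convention; NIfTI files, which use RAS, are
converted through an explicit x/y axis flip on reading and writing. Getting
this mapping and the DICOM/NIfTI scale factors (`RescaleSlope`/`Intercept`,
`scl_slope`/`scl_inter`) right is not cosmetic: mishandled scale factors in
format conversion are a documented way to corrupt counts by large factors
while images still *look* fine. The I/O layer therefore guarantees
round-trip preservation of totals to 0.1% (16-bit quantization with a
per-series slope is the only loss), and the test suite cross-checks the
DICOM writer against an independent reader (pydicom).

Rigid transforms are 6-DOF: translations in mm, rotations in degrees as
fixed-axis Euler angles applied z, then y, then x, about a stated centre
(the registration routines default it to the volume centre). A transform
maps reference-frame coordinates to target-frame coordinates; "clockwise
rotation about the bed axis, viewed from the head end" is a negative
right-handed rotation about +z, and a test pins that sign with a marker.

## The synthetic phantom

`phantom_spec()` describes a Jaszczak-style cylindrical phantom: a uniform
radioactive compartment, cold spheres on a ring near the top, cold rod
sectors near the bottom, and an optional external fiducial vial. The default
fill emulates 740 MBq of Tc-99m in 6.1 L of water (0.1213 MBq/mL); the
cylinder height is derived so that the fillable volume is exactly 6.1 L, so
the default phantom holds 740 MBq by construction (voxelization leaves the
simulated total within ~0.01%). Sphere diameters (12.7-31.8 mm) and rod
diameters (6.4-11.1 mm) are nominal Jaszczak-class values, fully
configurable; the physical insert dimensions of any particular phantom are
not published values and the defaults must not be read as such.

Voxels are classified by their centre point — exact, testable geometry with
no anti-aliasing; partial-volume effects enter through the acquisition
point-spread function (PSF), not the geometry. `simulate_acquisition()`
blurs the activity with an isotropic Gaussian PSF (default FWHM 10 mm, a
typical reconstructed SPECT resolution), scales to a target total count
(default 6e7, i.e. 500k counts per view over 120 views), and Poisson-samples
with an explicit seed. This is reconstructed-image-level emulation: there is
no projection/OSEM/attenuation/scatter model, deliberately — the questions
this package answers (registration accuracy, QC stability, kinetics and
dose recovery) live downstream of reconstruction. Consequently, passing tests say nothing
about reconstruction artefacts, collimator response, dead time, or
scatter-driven quantification bias in real data.

The Gaussian blur is periodic (FFT); objects sit well inside the grid so
wrap-around is negligible, and the kernel is normalized so totals are
preserved exactly.

`make_rotation_study()` reproduces the design of a rotation experiment:
angles 0/5/10 degrees clockwise about the bed axis, three replicates, with
and without the fiducial — 18 studies, each paired with its exact
ground-truth transform, plus one extra 0-degree acquisition per fiducial
state used as the registration reference. Rotated phantoms are generated by
classifying the analytic geometry at inverse-transformed voxel centres, so
the ground truth involves no interpolation.

`make_patient_series()` builds the patient-like analogue: kidneys and a
liver with ramp-then-double-exponential kinetics inside a water body with a
bone (spine) cylinder for the CT, imaged at 1.5/5/24/240 h post-injection.
Kidney kinetics default to `A1 = 10` MBq, `lambda1 = 0.1`/h, `A2 = 5` MBq,
`lambda2 = 0.01`/h (absolute-time parameterization, linear uptake from
injection to the first scan); the calibration factor defaults to 5e-5
MBq/count, which puts peak kidney voxels near 700 counts and the 240-h scan
near 25 counts — deliberately low-count late imaging. The closed-form TIA
map is blurred with the same PSF as the acquisitions (blurring commutes with
time integration), so it remains an exact per-voxel reference even for the
blurred, noiseless pipeline; the dose reference is a direct triple-loop
convolution of that map.

## Rigid co-registration

Registration minimizes the mean squared voxel intensity error between the
reference volume and the target resampled through a 6-DOF rigid transform
(trilinear). The optimizer is a quasi-Newton (BFGS) loop with
central-difference numerical gradients (step 0.1 mm / 0.1 degree) and an
Armijo backtracking line search; millimetres and degrees are treated 1:1 in
parameter space. Stopping follows the stated rules: gradient max-norm below
1e-4, parameter-step max-norm below 1e-5, or 100 iterations, whichever
fires first. The cost is normalized by its value at the starting transform
so the gradient tolerance is scale-free; the trace reports unnormalized
costs. An optional (default on) coarse search over bed-axis rotations of
-15 to +15 degrees in 5-degree steps precedes the descent, because the rod
and sphere patterns create local minima under pure-rotation misalignment.

Two numerical choices deserve emphasis:

* **Support-masked cost.** The optimizer evaluates the cost over the
  reference object's support (voxels above 0.5% of the reference maximum,
  dilated by two voxels) rather than the full grid. With a full-grid mean,
  the set of in-field voxels changes discontinuously whenever the moving
  grid crosses a grid-aligned position, which jumps the mean by several
  percent and can trap the line search exactly at the identity. The support
  set is fixed in the reference frame, so the cost is continuous;
  transforms pushing more than 20% of the support out of the field are
  rejected with infinite cost, which also guards against the
  shrinking-overlap bias. The user-facing `mse_cost()` keeps the plain
  contract (mean over all in-field voxels, with a validity count) for
  reporting. With the masked cost, 20 random 6-DOF perturbations up to
  10 degrees / 10 mm per axis on the noisy phantom are recovered with a
  maximum error of about 0.1 degree / 0.1 mm.
* **Validity masks, not zero fill.** Reslicing never silently zero-fills:
  out-of-field voxels are flagged in a `"valid"` attribute that downstream
  consumers must consult.

The normalized-cross-correlation cost (`ncc_cost`) emulates an SPM-style
comparator: both volumes Gaussian-smoothed at 7 mm FWHM, Pearson
correlation over samples taken every 4 mm, negated. It shares the optimizer
and exists for comparison, not as the native cost.

`set_origin_on_fiducial()` reproduces the marker-based origin convention:
the fiducial is detected as the hottest 26-connected component outside the
main object (largest component above 10% of the global maximum, dilated),
thresholded at 90% of the remaining maximum; ties break deterministically
(peak intensity, then size, then lowest linear index, with a warning).

## Registration quality and phantom QC

`percent_rmse()` is the registration-quality metric: the root-mean-square
voxel count difference between reference and registered volume, expressed
relative to the total counts of the reference (`100 * RMSE / sum(ref)`).
The RMSE is computed with the square root (the name says root-mean-square),
over the 3-D volume by default, with per-slice values available; a
per-voxel-mean normalization is available behind a flag but excluded from
default reports. Note that with the total-counts normalization, %RMSE is
invariant under joint rescaling of both volumes but does depend on the voxel
count, so values are comparable only within one acquisition geometry.

Integral uniformity follows the IAEA/NEMA form: each transverse slice is
smoothed with the 3x3 weighted ([1 2 1] x [1 2 1] / 16) kernel and
`100 (max - min)/(max + min)` is evaluated over a central cylindrical region
(75% of the phantom radius, in the band between the rod sectors and the
sphere plane), averaged over slices. Cold-sphere contrast compares the
minimum and mean counts in each sphere with a user-defined uniform
background disk: `100 (B - min)/B` and `100 (B - mean)/B`. Resolution fits
a count profile through a rod row as a constant baseline plus one Gaussian
per rod and reports FWHM = 2 sqrt(2 ln 2) sigma in mm, always mm. Automatic
peak detection (local extrema above 3x a robust noise MAD with a prominence
floor, minimum separation one rod pitch) works for sparse profiles; densely
packed blurred rods leave no baseline between dips, so the phantom QC path
anchors the Gaussians at the rod positions known from the geometry instead.
Fits that fail to converge are flagged per rod, never fatal.

On the noiseless default phantom the uniformity is ~0.003% — essentially
the interpolation floor — so *relative* changes of uniformity under
resampling are changes of a metric at its noise floor. The QC-stability
check is therefore phrased as bounded *degradation*: after registering and
reslicing a rotated noiseless phantom, non-uniformity and FWHM may not rise,
and maximum sphere contrast may not fall, by more than 5% relative;
improvements (trilinear reslicing slightly smooths the volume, which lowers
measured non-uniformity) are not failures. This operationalizes "no loss of
uniformity, contrast, or resolution". Sub-resolution spheres (diameter near
the PSF) have strongly position-dependent contrast on a 4 mm grid; the
group metric uses the maximum contrast over the sphere set, which is
carried by the well-resolved spheres.

## Kinetics: per-voxel time-integrated activity

Each voxel's time-activity curve is integrated as: trapezoid over the
uptake period — from injection (t = 0, A = 0 under the default
`ramp_from_zero`) to the per-voxel peak — plus the analytic tail of a
fitted decay model from the peak to infinity. The decay model is
`A1 exp(-lambda1 u) + A2 exp(-lambda2 u)` in time-since-peak `u`, fitted to
the points at and after the peak by bounded Levenberg-Marquardt
(amplitudes >= 0, lambda in [1e-5, 10]/h), initialized by biexponential
peeling. The tail integral `A1/lambda1 + A2/lambda2` — not the individual
parameters — is the contracted output: with the typical 4-point schedule the
double exponential sits at the identifiability edge and parameters can
trade off while the integral stays stable (the tests assert exactly this).

Fallbacks are explicit and recorded per voxel: mono-exponential when fewer
than 3 post-peak points remain or the double fit fails; physical-decay
extrapolation from the last point when the mono fit also fails (requires
the radionuclide half-life). When the half-life is supplied, the fitted
decay constants are floored at the physical decay constant: effective
clearance cannot be slower than physical decay, and without the floor a
noisy slow component can park at a near-zero rate and inflate the tail by
orders of magnitude (we observed ~40x kidney-dose inflation before adding
it). Voxels whose fitted effective decay sits at the physical rate are
counted and reported as a warning when they exceed a configurable fraction.

`tia_map()` applies the counts-to-activity calibration (MBq per count),
fits only voxels whose peak reaches a noise floor (default 1% of the series
maximum — background is never fitted, by contract it is exactly 0), and
returns MBq·s. Reconstructed counts are taken as-is: no decay correction is
assumed to have been applied upstream, and no partial-volume or
recovery-coefficient correction is attempted.

## Dosimetry

Bone is segmented from the CT at >= 300 HU (inclusive threshold,
documented). The dose map is
`dose(v) = sum_s TIA(s) K_m(s)(v - s)` with the kernel chosen by the
*source* voxel's medium: sources are split by tissue, each group is
convolved with its medium's kernel by zero-padded FFT (pad sizes rounded to
2-3-5-smooth lengths), and the results are summed. "Source medium" is a
documented choice behind one switch — kernel tables are indexed by the
emitting medium — where "differentiate S values between bone and soft
tissue" is ambiguous between source and target. Kernel spacing must match
the TIA grid exactly; mismatches are an error, never silently resampled.
The FFT path is verified against a direct triple-loop sum (`brute_force_dose`)
to 1e-10 relative on random instances, and interior sources conserve
`sum(dose) = sum(TIA) x sum(kernel)` to 1e-9.

The shipped kernels are *synthetic*: an analytic self-dose term (local
deposition of the mean beta energy in the source-voxel mass) plus an
exponential-attenuation / inverse-square cross-dose term, with stronger
attenuation and higher density in bone. They have the right shape, ordering
(bone <= soft tissue off-centre) and rough magnitude (Lu-177 soft-tissue
self-dose ~0.3 mGy per MBq·s in a 4 mm voxel), and their provenance field
says "synthetic toy kernel - not for clinical use". Monte-Carlo-grade
S-value tables are out of scope by design; the kernel file contract (JSON
with radionuclide, spacing, medium, provenance, dimensions, values) lets
users drop in real tables.

The VOI at a cutoff keeps the voxels at or above 40% (inclusive) of the
maximum dose within an organ region and takes the 26-connected component
containing the maximum; connectivity is a documented choice where
"all supra-threshold voxels" would also have been defensible.
Method-comparison utilities (Pearson correlation, Bland-Altman with 1.96 SD
limits of agreement) operate on paired per-patient doses.

## Pipeline and phantom experiment

`run_dosimetry()` wires the stages — load, co-registration of every later
time point to the first acquisition (the first scan is the reference, the
patient analogue of registering rotated phantoms to the unrotated scan),
activity integration, bone segmentation, kernel convolution, VOI report —
with every stage output written to disk (NIfTI volumes, JSON transforms and
reports, a DICOM dose-map series) and a manifest recording package version,
seed, per-stage wall times (informational only, never asserted) and a
configuration fingerprint. A stage failure aborts with the stage name;
completed outputs stay on disk.

`run_phantom_experiment()` is the harness for the 18-study rotation
experiment: it simulates, registers, reslices and reports per-study
recovery errors, %RMSE before/after, and QC metrics, plus group mean/SD per
angle x fiducial cell — the synthetic analogue of a rotation-study results
table. The fiducial null finding is restated as a testable property of this
implementation: group-mean %RMSE with and without the marker differ by less
than two pooled standard deviations.

## Problem sizes and error budgets used in validation

The validation suite runs the rotation experiment at the full default size
(128^3 at 4 mm, 18 studies plus 2 references, Poisson noise at 6e7 counts);
unit tests use a 64^3 field of view over the same physical phantom. The
synthetic patient uses 64^3 at 4 mm with ~5,700 fitted voxels per TIA map.
Budgets asserted by the acceptance tests: >= 90% of the 18 studies within
0.5 degree and half a voxel (2 mm); noiseless per-voxel TIA within 1% and
noisy median within 10% over 100 curves; noiseless kidney mean dose within
5% and noisy median within 15% over 10 seeds; FFT-vs-direct convolution
within 1e-10; DICOM/NIfTI total-count round trips within 0.1%.

## Known limitations

* Reconstructed-image-level simulation only; no projection-domain physics.
* Rigid registration only — organs that move relative to each other are
  mis-registered by construction, and doses of mobile lesions will be
  biased; deformable registration is out of scope.
* Intramodality SPECT-to-SPECT registration; SPECT-to-CT alignment is
  assumed from the scanner.
* At the default 10 mm PSF on 4 mm voxels the volumes are marginally
  sampled: a reslice-and-invert round trip leaves ~1.6% RMS of max
  (interpolation), dropping below 1% for band-limited volumes (PSF >= 4
  voxels FWHM).
* No contrast-recovery (partial volume) correction in the kinetics chain.
* The toy S-value kernels support verification of the convolution
  machinery, not clinical dose numbers.
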
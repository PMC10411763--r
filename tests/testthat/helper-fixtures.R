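# Shared fixtures. Expensive simulations are cached per test run so several
# test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Full-size phantom at the default 128^3 grid.
default_spec <- function() cached("default_spec", phantom_spec())

# Reduced 64^3 grid (same physical phantom, same 4 mm voxels cover it) for
# unit tests where registration accuracy, not scale, is under test. The
# tighter field of view forces the fiducial onto the diagonal.
small_spec <- function() cached("small_spec",
  phantom_spec(grid_shape = c(64, 64, 64),
               fiducial = list(volume_ml = 3.0, position = c(93, 93, 0))))

small_phantom_noiseless <- function() cached("small_phantom_noiseless", {
  simulate_acquisition(make_phantom(small_spec())$activity,
                       seed = 1, poisson = FALSE)
})

# Random small volume pair on a common grid.
random_volume <- function(dim = c(8, 8, 8), seed = 1, spacing = c(4, 4, 4)) {
  set.seed(seed)
  volume3d(array(stats::runif(prod(dim)), dim), spacing = spacing,
           value_kind = "counts")
}

# Patient-series fixtures (noiseless / one noisy seed) with toy Lu-177
# kernels, shared across kinetics, dosimetry and pipeline tests.
patient_fixture <- function() cached("patient_fixture", {
  ps <- make_patient_series()
  kernels <- list(
    soft_tissue = generate_toy_kernel("Lu177", ps$series[[1]]$spacing[1]),
    bone = generate_toy_kernel("Lu177", ps$series[[1]]$spacing[1],
                               medium = "bone"))
  bone <- segment_bone(ps$ct)
  ref_dose <- brute_force_dose(ps$analytic_tia, kernels, bone)
  list(ps = ps, kernels = kernels, bone = bone, ref_dose = ref_dose,
       kidney_seed = c(-45, 20, -10))
})
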
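# Run code with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Periodic (FFT) isotropic Gaussian blur of a 3-D array; sigma given per axis
# in voxels. Objects are assumed to sit well inside the grid, so wrap-around
# leakage is negligible; the kernel is normalized to unit sum, preserving
# totals exactly.
gaussian_blur_fft <- function(values, sigma_vox) {
  d <- dim(values)
  if (all(sigma_vox <= 0)) return(values)
  g1 <- function(n, s) {
    if (s <= 0) return(c(1, rep(0, n - 1)))
    x <- seq_len(n) - 1
    x <- pmin(x, n - x)               # wrapped distance from index 0
    g <- exp(-0.5 * (x / s)^2)
    g / sum(g)
  }
  K <- outer(outer(g1(d[1], sigma_vox[1]), g1(d[2], sigma_vox[2])),
             g1(d[3], sigma_vox[3]))
  dim(K) <- d
  out <- Re(fft(fft(values) * fft(K), inverse = TRUE)) / prod(d)
  pmax(out, 0)
}

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

# In-slice 3x3 NEMA-style weighted smoothing ([1 2 1] x [1 2 1] / 16,
# edge-replicated), applied slice by slice along the third axis.
smooth_slices_3x3 <- function(values) {
  d <- dim(values)
  out <- values
  w <- outer(c(1, 2, 1), c(1, 2, 1)) / 16
  pad <- function(m) m[c(1, seq_len(nrow(m)), nrow(m)), c(1, seq_len(ncol(m)), ncol(m))]
  for (k in seq_len(d[3])) {
    m <- pad(values[, , k])
    acc <- matrix(0, d[1], d[2])
    for (di in 0:2) for (dj in 0:2)
      acc <- acc + w[di + 1, dj + 1] * m[di + seq_len(d[1]), dj + seq_len(d[2])]
    out[, , k] <- acc
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
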
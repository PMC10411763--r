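#' Configure rigid co-registration
#'
#' Stopping rules follow the in-house optimizer contract: a gradient
#' tolerance of 1e-4 and a convergence (parameter-step) tolerance of 1e-5,
#' within at most 100 iterations. The gradient tolerance applies to the
#' max-norm of the gradient of the cost normalized by its value at the
#' starting transform (so it is scale-free); the convergence tolerance to the
#' max-norm of the parameter update in mm / degrees.
#'
#' For the normalized cross-correlation cost (emulating an SPM-style
#' comparator) the defaults add 7 mm FWHM Gaussian pre-smoothing and a 4 mm
#' average sample spacing.
#'
#' @param cost `"mse"` (mean squared intensity error, the native cost) or
#'   `"ncc"` (negated normalized cross-correlation).
#' @param gradient_tol,convergence_tol,max_iterations stopping rules.
#' @param smoothing_fwhm_mm Gaussian pre-smoothing FWHM; `NULL` means 0 for
#'   mse, 7 for ncc.
#' @param sample_spacing_mm spacing between cost sample points; `NULL` means
#'   the full grid for mse, 4 mm for ncc.
#' @param coarse_search run a coarse initial rotation search about the bed
#'   (z) axis, +/-15 degrees in 5-degree steps, before gradient descent.
#' @return an object of class `registration_config`.
#' @export
registration_config <- function(cost = c("mse", "ncc"),
                                gradient_tol = 1e-4,
                                convergence_tol = 1e-5,
                                max_iterations = 100L,
                                smoothing_fwhm_mm = NULL,
                                sample_spacing_mm = NULL,
                                coarse_search = TRUE) {
  cost <- match.arg(cost)
  if (gradient_tol <= 0 || convergence_tol <= 0)
    stop("tolerances must be positive", call. = FALSE)
  if (max_iterations < 1) stop("max_iterations must be >= 1", call. = FALSE)
  structure(list(
    cost = cost, gradient_tol = gradient_tol,
    convergence_tol = convergence_tol,
    max_iterations = as.integer(max_iterations),
    smoothing_fwhm_mm = smoothing_fwhm_mm %||% if (cost == "ncc") 7 else 0,
    sample_spacing_mm = sample_spacing_mm %||%
      if (cost == "ncc") 4 else NULL,
    coarse_search = isTRUE(coarse_search)),
    class = "registration_config")
}

#' Mean squared intensity error between a reference and a transformed target
#'
#' The target is resampled through the rigid transform onto the reference
#' grid (trilinear) and the mean over in-field voxels of the squared
#' intensity difference is returned. Out-of-field voxels are excluded from
#' the mean via a validity count, not zero-filled.
#'
#' @param reference,target [volume3d()]s.
#' @param transform a [rigid_transform()] mapping reference world coordinates
#'   to target world coordinates (default identity).
#' @return the mean squared error, with attribute `n_valid` (number of
#'   in-field voxels).
#' @export
mse_cost <- function(reference, target, transform = rigid_transform()) {
  M <- index_affine(reference, target, transform)
  r <- cpp_ssd_affine(as.numeric(reference$values), dim(reference$values),
                      as.numeric(target$values), dim(target$values), M)
  if (r$n == 0) stop("empty overlap between reference and transformed target",
                     call. = FALSE)
  structure(r$ssd / r$n, n_valid = r$n)
}

#' Negated normalized cross-correlation cost
#'
#' Both volumes are pre-smoothed with a Gaussian (`config$smoothing_fwhm_mm`)
#' and the Pearson correlation is computed over sample points taken every
#' `config$sample_spacing_mm` on the reference grid; the cost is its
#' negative, so perfectly correlated volumes score -1.
#'
#' @inheritParams mse_cost
#' @param config a [registration_config()] (cost `"ncc"`).
#' @return negated correlation in `[-1, 1]`.
#' @export
ncc_cost <- function(reference, target, transform = rigid_transform(),
                     config = registration_config("ncc")) {
  sm <- function(v) {
    if (config$smoothing_fwhm_mm <= 0) return(v)
    new_volume_like(v, gaussian_blur_fft(
      v$values, config$smoothing_fwhm_mm * FWHM_TO_SIGMA / v$spacing))
  }
  rs <- sm(reference); ts <- sm(target)
  coarse <- subsample_volume(rs, config$sample_spacing_mm)
  M <- index_affine(coarse, ts, transform)
  res <- cpp_affine_resample(as.numeric(ts$values), dim(ts$values),
                             dim(coarse$values), M, 0L)
  ok <- res$valid
  if (!any(ok)) stop("empty overlap", call. = FALSE)
  a <- as.numeric(coarse$values)[ok]
  b <- res$values[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero-variance input to ncc_cost", call. = FALSE)
  -stats::cor(a, b)
}

subsample_volume <- function(volume, spacing_mm) {
  if (is.null(spacing_mm)) return(volume)
  step <- pmax(1L, round(spacing_mm / volume$spacing))
  d <- dim(volume$values)
  idx <- lapply(1:3, function(a) seq(1L, d[a], by = step[a]))
  volume3d(volume$values[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
           spacing = volume$spacing * step, origin = volume$origin,
           orientation = volume$orientation, value_kind = volume$value_kind,
           acquisition_time_h = volume$acquisition_time_h)
}

#' Rigid co-registration by cost minimization
#'
#' Finds the 6-degree-of-freedom rigid transform mapping the reference onto
#' the target that minimizes the configured cost, by quasi-Newton (BFGS)
#' descent with central-difference numerical gradients. Optimization starts
#' from the identity, optionally preceded by a coarse rotation search about
#' the bed (z) axis. Iteration stops when the normalized-gradient max-norm
#' falls below `gradient_tol`, the parameter step max-norm falls below
#' `convergence_tol`, or `max_iterations` is reached; the `converged` field
#' records which rule fired. Degrees and millimetres are treated 1:1 in
#' parameter space.
#'
#' @param reference,target [volume3d()]s of the same value kind.
#' @param config a [registration_config()].
#' @return an object of class `registration_result`: `transform`,
#'   `final_cost`, `iterations`, `converged`, `stop_rule`, `cost_trace`.
#' @export
register_rigid <- function(reference, target,
                           config = registration_config()) {
  if (!identical(reference$value_kind, target$value_kind))
    stop("reference and target must have the same value_kind", call. = FALSE)
  center <- volume_center(reference)
  par_tr <- function(p) rigid_transform(p[1], p[2], p[3], p[4], p[5], p[6],
                                        center = center)
  if (config$cost == "mse") {
    ref_c <- subsample_volume(reference, config$sample_spacing_mm)
    if (config$smoothing_fwhm_mm > 0) {
      sg <- config$smoothing_fwhm_mm * FWHM_TO_SIGMA
      ref_c <- new_volume_like(ref_c, gaussian_blur_fft(ref_c$values, sg / ref_c$spacing))
      tgt_c <- new_volume_like(target, gaussian_blur_fft(target$values, sg / target$spacing))
    } else tgt_c <- target
    # Two sampling choices keep the cost surface smooth:
    # (1) evaluate over the reference object's support (plus a margin),
    #     fixed in the reference frame, so the mean does not jump when the
    #     moving grid crosses grid-aligned positions;
    # (2) sample both volumes at half-voxel-shifted points, so the identity
    #     transform carries the same trilinear noise-smoothing as its
    #     neighbourhood — with on-grid sampling, interpolation smooths the
    #     target's noise everywhere except at grid-aligned transforms,
    #     carving a spurious minimum a fraction of a degree away.
    rdim_c <- dim(ref_c$values)
    half <- rep(0.5, 3)
    Mh <- cbind(diag(3), half)
    ref_vec <- cpp_affine_resample(as.numeric(ref_c$values), rdim_c,
                                   rdim_c, Mh, 0L)$values
    supp <- ref_vec > 0.005 * max(ref_vec)
    supp <- cpp_conv3_direct(as.numeric(supp), rdim_c, rep(1, 125),
                             c(5L, 5L, 5L)) > 1e-9
    idx0 <- which(supp) - 1L
    n_supp <- length(idx0)
    tgt_vec <- as.numeric(tgt_c$values)
    tdim_c <- dim(tgt_c$values)
    rawcost <- function(p) {
      M <- index_affine(ref_c, tgt_c, par_tr(p))
      M[, 4] <- M[, 4] + drop(M[, 1:3] %*% half)
      r <- cpp_ssd_affine_mask(ref_vec, rdim_c, tgt_vec, tdim_c, M, idx0)
      # reject transforms that push a meaningful part of the object out of
      # the field instead of letting shrinking overlap lower the mean
      if (r$n < 0.8 * n_supp) return(Inf)
      r$ssd / r$n
    }
  } else {
    rawcost <- function(p) ncc_cost(reference, target, par_tr(p), config)
  }

  p <- numeric(6)
  if (config$coarse_search) {
    grid <- seq(-15, 15, by = 5)
    costs <- vapply(grid, function(a) rawcost(c(0, 0, 0, 0, 0, a)), 0)
    p[6] <- grid[which.min(costs)]
  }
  c_init <- rawcost(p)
  if (!is.finite(c_init))
    stop("non-finite cost at the starting transform", call. = FALSE)
  if (c_init == 0) {
    # the starting transform is already a perfect match (identical volumes)
    return(structure(list(transform = par_tr(p), final_cost = 0,
                          iterations = 0L, converged = TRUE,
                          stop_rule = "gradient", cost_trace = 0),
                     class = "registration_result"))
  }
  # Normalize so the stopping tolerances are scale-free; for ncc the cost is
  # already dimensionless and can cross zero, so shift instead of divide.
  f <- if (config$cost == "ncc") function(p) rawcost(p) + 1
       else function(p) rawcost(p) / c_init
  grad <- function(p, h = 0.1) {
    g <- numeric(6)
    for (i in 1:6) {
      e <- numeric(6); e[i] <- h
      g[i] <- (f(p + e) - f(p - e)) / (2 * h)
    }
    g
  }

  trace <- f(p)
  H <- diag(6)
  g <- grad(p)
  iter <- 0L
  rule <- "max_iterations"
  fp <- trace[1]
  while (iter < config$max_iterations) {
    iter <- iter + 1L
    if (max(abs(g)) < config$gradient_tol) { rule <- "gradient"; break }
    d <- drop(-H %*% g)
    gd <- sum(g * d)
    if (!is.finite(gd) || gd >= 0) { H <- diag(6); d <- -g; gd <- -sum(g * g) }
    step <- 1
    repeat {
      pn <- p + step * d
      fn <- f(pn)
      if (is.finite(fn) && fn <= fp + 1e-4 * step * gd) break
      step <- step / 2
      if (step < 1e-12) { pn <- p; fn <- fp; break }
    }
    s <- pn - p
    trace <- c(trace, fn)
    if (max(abs(s)) < config$convergence_tol) {
      p <- pn; fp <- fn; rule <- "step"; break
    }
    gn <- grad(pn)
    y <- gn - g
    sy <- sum(s * y)
    if (is.finite(sy) && sy > 1e-12) {
      rho <- 1 / sy
      I6 <- diag(6)
      V <- I6 - rho * outer(s, y)
      H <- V %*% H %*% t(V) + rho * outer(s, s)
    }
    p <- pn; g <- gn; fp <- fn
  }
  final_raw <- rawcost(p)
  structure(list(transform = par_tr(p), final_cost = final_raw,
                 iterations = iter,
                 converged = rule %in% c("gradient", "step"),
                 stop_rule = rule,
                 cost_trace = if (config$cost == "ncc") trace - 1
                              else trace * c_init),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> %d iterations, %s (%s)\n", x$iterations,
              if (x$converged) "converged" else "stopped", x$stop_rule))
  cat(sprintf("  final cost %.6g\n", x$final_cost))
  print(x$transform)
  invisible(x)
}

#' Reslice a target volume onto a reference grid through a rigid transform
#'
#' @param target [volume3d()] to reslice.
#' @param transform [rigid_transform()] mapping reference coordinates to
#'   target coordinates (as recovered by [register_rigid()]).
#' @param reference_grid [volume3d()] defining the output grid.
#' @param interp `"trilinear"` or `"nearest"`.
#' @return [volume3d()] on the reference grid with a `"valid"` mask
#'   attribute for out-of-field voxels.
#' @export
reslice <- function(target, transform, reference_grid,
                    interp = c("trilinear", "nearest")) {
  interp <- match.arg(interp)
  M <- index_affine(reference_grid, target, transform)
  res <- cpp_affine_resample(as.numeric(target$values), dim(target$values),
                             dim(reference_grid$values), M,
                             if (interp == "trilinear") 0L else 1L)
  vals <- array(res$values, dim(reference_grid$values))
  out <- volume3d(vals, spacing = reference_grid$spacing,
                  origin = reference_grid$origin,
                  orientation = reference_grid$orientation,
                  value_kind = target$value_kind,
                  acquisition_time_h = target$acquisition_time_h)
  attr(out, "valid") <- array(res$valid, dim(reference_grid$values))
  out
}

#' Set the volume origin on a fiducial marker
#'
#' Translates the volume origin so that the fiducial centroid lies at world
#' (0,0,0). The fiducial is found automatically as the hottest connected
#' component (26-connectivity) outside the main object: the main object is
#' the largest component above 10% of the global maximum, dilated by two
#' voxels; among the remaining voxels, candidates are components above 90%
#' of the remaining maximum. Ties between candidates of equal peak intensity
#' are broken by larger volume, then by lowest linear index, with a warning.
#'
#' @param volume a [volume3d()].
#' @param method `"centroid_of_hottest_component"` or `"manual_point"`.
#' @param point world coordinates (mm) of the marker for `"manual_point"`.
#' @return the volume with its origin shifted.
#' @export
set_origin_on_fiducial <- function(volume,
                                   method = c("centroid_of_hottest_component",
                                              "manual_point"),
                                   point = NULL) {
  method <- match.arg(method)
  if (method == "manual_point") {
    if (is.null(point)) stop("manual_point requires `point`", call. = FALSE)
    centroid <- as.numeric(point)
  } else {
    v <- volume$values
    d <- dim(v)
    mx <- max(v)
    if (mx <= 0) stop("no signal in volume", call. = FALSE)
    main_mask <- v >= 0.1 * mx
    lab <- array(cpp_label26(main_mask, d), d)
    sizes <- tabulate(lab[lab > 0])
    main_id <- which.max(sizes)
    main_dil <- cpp_conv3_direct(as.numeric(lab == main_id), d,
                                 rep(1, 125), c(5L, 5L, 5L)) > 1e-9
    outside <- !array(main_dil, d)
    mx_out <- max(v[outside])
    if (mx_out < 0.05 * mx)
      stop("no fiducial candidate found outside the main object", call. = FALSE)
    cand_mask <- outside & v >= 0.9 * mx_out
    clab <- array(cpp_label26(cand_mask, d), d)
    ids <- sort(unique(clab[clab > 0]))
    if (length(ids) == 0)
      stop("no fiducial candidate found outside the main object", call. = FALSE)
    peak <- vapply(ids, function(i) max(v[clab == i]), 0)
    vol <- vapply(ids, function(i) sum(clab == i), 0L)
    first_idx <- vapply(ids, function(i) which(clab == i)[1], 0L)
    ord <- order(-peak, -vol, first_idx)
    if (length(ids) > 1 && abs(peak[ord[1]] - peak[ord[2]]) < 1e-12)
      warning("multiple fiducial candidates with equal peak intensity; ",
              "picking the largest, then lowest-index component")
    pick <- ids[ord[1]]
    idx <- which(clab == pick, arr.ind = TRUE) - 1
    w <- v[clab == pick]
    pts <- index_to_world(volume, idx)
    centroid <- colSums(pts * w) / sum(w)
  }
  volume$origin <- volume$origin - centroid
  volume
}
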
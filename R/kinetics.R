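#' Counts-to-activity calibration factor
#'
#' @param mbq_per_count calibration in MBq per reconstructed count (> 0).
#' @param reference free-text note on how the factor was obtained.
#' @return object of class `calibration_factor`.
#' @export
calibration_factor <- function(mbq_per_count, reference = "") {
  if (!is.finite(mbq_per_count) || mbq_per_count <= 0)
    stop("mbq_per_count must be positive", call. = FALSE)
  structure(list(mbq_per_count = mbq_per_count, reference = reference),
            class = "calibration_factor")
}

#' Fit double-exponential decay kinetics to a time-activity curve
#'
#' Fits `A1 exp(-lambda1 u) + A2 exp(-lambda2 u)`, with `u` the time since
#' the curve peak, to the points at and after the peak, by bounded nonlinear
#' least squares (amplitudes >= 0, decay constants in [1e-5, 10] per hour),
#' initialized by biexponential peeling (log-linear fit of the last two
#' points for the slow component, residual for the fast). With fewer than 3
#' post-peak points, or when the double-exponential fit fails, a
#' mono-exponential fit is used; when that also fails, physical-decay
#' extrapolation from the last point (requires `half_life_h`). The `model`
#' field records which branch ran.
#'
#' The analytic tail integral from the peak to infinity,
#' `A1/lambda1 + A2/lambda2` (MBq h), is the contracted output: with a
#' 4-point series the double-exponential sits at the identifiability edge
#' and individual parameters may be non-unique, but the integral is stable.
#'
#' @param times_h acquisition times, hours, strictly increasing.
#' @param activities_MBq non-negative activities, MBq.
#' @param half_life_h physical half-life (hours). When supplied it enables
#'   the last-resort physical-decay fallback and floors the fitted decay
#'   constants at the physical decay constant: effective clearance cannot be
#'   slower than physical decay, and without this floor a noisy slow
#'   component can park at a near-zero decay constant and inflate the tail
#'   integral by orders of magnitude.
#' @return object of class `decay_fit`: `A1`, `A2` (MBq, amplitudes at the
#'   peak time), `lambda1`, `lambda2` (1/h), `peak_index`, `t_peak_h`,
#'   `tail_integral` (MBq h, from the peak to infinity), `model`,
#'   `fit_residual` (relative RMS).
#' @export
fit_decay_double_exp <- function(times_h, activities_MBq, half_life_h = NULL) {
  t <- as.numeric(times_h); a <- as.numeric(activities_MBq)
  if (length(t) != length(a)) stop("length mismatch", call. = FALSE)
  if (any(diff(t) <= 0)) stop("times_h must be strictly increasing", call. = FALSE)
  if (any(a < 0)) stop("activities must be non-negative", call. = FALSE)
  peak <- which.max(a)
  if (all(a == 0))
    return(new_decay_fit(0, 1, 0, 1, peak, t[peak], "double_exp", 0, 0))
  u <- t[peak:length(t)] - t[peak]
  y <- a[peak:length(t)]
  n_post <- length(u)
  if (n_post < 2 && is.null(half_life_h))
    stop("fewer than 2 post-peak points and no half_life_h supplied",
         call. = FALSE)

  relrms <- function(pred) sqrt(mean((pred - y)^2)) / max(y)
  lmin <- if (is.null(half_life_h)) 1e-5 else
    max(1e-5, log(2) / half_life_h)
  fit <- NULL
  if (n_post >= 3) {
    st <- peel_start(u, y, lmin)
    fit <- tryCatch({
      m <- minpack.lm::nlsLM(
        y ~ A1 * exp(-l1 * u) + A2 * exp(-l2 * u),
        data = data.frame(u = u, y = y),
        start = st, lower = c(A1 = 0, l1 = lmin, A2 = 0, l2 = lmin),
        upper = c(A1 = Inf, l1 = 10, A2 = Inf, l2 = 10),
        control = minpack.lm::nls.lm.control(maxiter = 200))
      cf <- stats::coef(m)
      if (any(!is.finite(cf))) stop("non-finite fit")
      new_decay_fit(cf["A1"], cf["l1"], cf["A2"], cf["l2"], peak, t[peak],
                    "double_exp", relrms(stats::predict(m)), NULL)
    }, error = function(e) NULL)
    if (!is.null(fit) && !is.finite(fit$tail_integral)) fit <- NULL
  }
  if (is.null(fit) && n_post >= 2) {
    fit <- tryCatch({
      pos <- y > 0
      if (sum(pos) >= 2) {
        lf <- stats::lm(log(y[pos]) ~ u[pos])
        l0 <- max(lmin, min(10, -stats::coef(lf)[2]))
        A0 <- min(exp(stats::coef(lf)[1]), 10 * max(y))
      } else { l0 <- max(0.1, lmin); A0 <- max(y) }
      m <- minpack.lm::nlsLM(
        y ~ A * exp(-l * u), data = data.frame(u = u, y = y),
        start = list(A = A0, l = l0), lower = c(A = 0, l = lmin),
        upper = c(A = Inf, l = 10),
        control = minpack.lm::nls.lm.control(maxiter = 200))
      cf <- stats::coef(m)
      if (any(!is.finite(cf))) stop("non-finite fit")
      new_decay_fit(cf["A"], cf["l"], 0, 1, peak, t[peak], "mono_exp",
                    relrms(stats::predict(m)), NULL)
    }, error = function(e) NULL)
    if (!is.null(fit) && !is.finite(fit$tail_integral)) fit <- NULL
  }
  if (is.null(fit)) {
    if (is.null(half_life_h))
      stop("decay fit failed and no half_life_h supplied for the physical",
           "-decay fallback", call. = FALSE)
    lphys <- log(2) / half_life_h
    # observed segment peak -> last by trapezoid, then physical decay from
    # the last point
    obs <- if (n_post >= 2) sum(diff(u) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
           else 0
    tail_int <- obs + y[n_post] / lphys
    fit <- new_decay_fit(y[n_post], lphys, 0, 1, peak, t[peak],
                         "physical_decay_fallback", 0, tail_int)
  }
  fit
}

#' Construct a decay fit from known parameters
#'
#' Builds a `decay_fit` object directly, e.g. from ground-truth kinetics,
#' without fitting. Amplitudes are at the peak time; `u = t - t_peak_h`.
#'
#' @param A1,A2 amplitudes at the peak, MBq.
#' @param lambda1,lambda2 decay constants, 1/h.
#' @param peak_index index of the peak point in the associated series.
#' @param t_peak_h peak time, hours.
#' @param model model label.
#' @return a `decay_fit`.
#' @export
decay_fit <- function(A1, lambda1, A2 = 0, lambda2 = 1, peak_index = 1L,
                      t_peak_h = 0, model = "double_exp") {
  if (lambda1 <= 0 || lambda2 <= 0)
    stop("decay constants must be positive", call. = FALSE)
  new_decay_fit(A1, lambda1, A2, lambda2, peak_index, t_peak_h, model, NA_real_,
                NULL)
}

new_decay_fit <- function(A1, l1, A2, l2, peak, t_peak, model, resid,
                          tail_override) {
  tail_int <- tail_override %||% (A1 / l1 + A2 / l2)
  structure(list(A1 = unname(A1), A2 = unname(A2), lambda1 = unname(l1),
                 lambda2 = unname(l2), peak_index = peak, t_peak_h = t_peak,
                 tail_integral = unname(tail_int), model = model,
                 fit_residual = unname(resid)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> %s: A1=%.4g MBq l1=%.4g /h, A2=%.4g MBq l2=%.4g /h\n",
              x$model, x$A1, x$lambda1, x$A2, x$lambda2))
  cat(sprintf("  peak at point %d (t=%.3g h); tail integral %.5g MBq h; rel RMS %.3g\n",
              x$peak_index, x$t_peak_h, x$tail_integral, x$fit_residual))
  invisible(x)
}

# Biexponential peeling start values: slow component from a log-linear fit
# of the last two points, fast from the residual of the first points.
# Amplitudes are clamped to a multiple of the observed peak so a zero last
# sample cannot blow the start values up.
peel_start <- function(u, y, lmin = 1e-5) {
  n <- length(u)
  yl <- pmax(y, max(y) * 1e-9)
  l2 <- (log(yl[n - 1]) - log(yl[n])) / (u[n] - u[n - 1])
  l2 <- max(lmin, min(10, l2))
  A2 <- min(yl[n] * exp(l2 * u[n]), 10 * max(y))
  if (!is.finite(A2)) A2 <- max(y)
  r <- y - A2 * exp(-l2 * u)
  pos <- which(r > 0 & seq_along(r) <= 2)
  if (length(pos) >= 2) {
    l1 <- (log(r[pos[1]]) - log(r[pos[2]])) / (u[pos[2]] - u[pos[1]])
    l1 <- max(l2 * 2, min(10, l1))
    A1 <- r[pos[1]] * exp(l1 * u[pos[1]])
  } else {
    l1 <- min(10, l2 * 10)
    A1 <- max(r, 0.1 * max(y))
  }
  list(A1 = max(A1, 0), l1 = l1, A2 = max(A2, 0), l2 = l2)
}

# Model value at time-since-peak u.
predict_decay <- function(fit, u) {
  fit$A1 * exp(-fit$lambda1 * u) + fit$A2 * exp(-fit$lambda2 * u)
}

#' Time-integrated activity of a time-activity curve
#'
#' Integrates the curve from injection (t = 0) to infinity: the uptake
#' period, from injection to the per-curve peak, by the trapezoidal rule
#' (with A(0) = 0 under `"ramp_from_zero"`, or A(0) = A(t1) under
#' `"flat_from_first"`), plus the analytic tail of the fitted decay model
#' from the peak to infinity.
#'
#' @param times_h,activities_MBq the observed curve.
#' @param fit a [fit_decay_double_exp()] result for this curve.
#' @param uptake_model `"ramp_from_zero"` or `"flat_from_first"`.
#' @return time-integrated activity in MBq h.
#' @export
integrate_tac <- function(times_h, activities_MBq, fit,
                          uptake_model = c("ramp_from_zero",
                                           "flat_from_first")) {
  uptake_model <- match.arg(uptake_model)
  t <- as.numeric(times_h); a <- as.numeric(activities_MBq)
  if (length(t) != length(a)) stop("length mismatch", call. = FALSE)
  if (fit$peak_index > length(t) || abs(t[fit$peak_index] - fit$t_peak_h) > 1e-9)
    stop("decay fit is inconsistent with the series", call. = FALSE)
  p <- fit$peak_index
  tu <- c(0, t[seq_len(p)])
  au <- c(if (uptake_model == "ramp_from_zero") 0 else a[1], a[seq_len(p)])
  uptake <- sum(diff(tu) * (utils::head(au, -1) + utils::tail(au, -1)) / 2)
  uptake + fit$tail_integral
}

#' Per-voxel time-integrated activity map from a co-registered series
#'
#' Converts counts to activity through the calibration factor, then fits and
#' integrates the time-activity curve of every voxel whose peak activity
#' reaches the noise floor (default 1% of the series maximum); voxels below
#' the floor get TIA 0, so pure noise is never fitted. The output is in
#' MBq s (hours converted at 3600 s/h).
#'
#' @param series list of co-registered [volume3d()]s of kind `"counts"`,
#'   each with `acquisition_time_h` set, on a common grid.
#' @param cal a [calibration_factor()].
#' @param noise_floor fraction of the series maximum below which a voxel is
#'   not fitted.
#' @param uptake_model passed to [integrate_tac()].
#' @param half_life_h optional physical half-life for the fallback branch
#'   and the decay-constant floor (see [fit_decay_double_exp()]).
#' @param slow_decay_warn_fraction warn when more than this fraction of
#'   fitted voxels shows effective decay at or slower than physical decay.
#' @return a [volume3d()] of kind `"tia_MBq_s"`, with attribute
#'   `"model_counts"`: a table of how many voxels used each decay-model
#'   branch.
#' @export
tia_map <- function(series, cal, noise_floor = 0.01,
                    uptake_model = "ramp_from_zero", half_life_h = NULL,
                    slow_decay_warn_fraction = 0.25) {
  if (length(series) < 2) stop("need a series of volumes", call. = FALSE)
  times <- vapply(series, function(v) v$acquisition_time_h, 0)
  if (anyNA(times))
    stop("every volume in the series needs acquisition_time_h; volumes ",
         "without acquisition times can be registered but not integrated",
         call. = FALSE)
  if (any(diff(times) <= 0))
    stop("series must be ordered by strictly increasing acquisition time",
         call. = FALSE)
  for (v in series[-1]) stopifnot_same_grid(series[[1]], v)
  A <- vapply(series, function(v) as.numeric(v$values) * cal$mbq_per_count,
              numeric(length(series[[1]]$values)))
  peak_val <- do.call(pmax, as.data.frame(A))
  floor_abs <- noise_floor * max(peak_val)
  sel <- which(peak_val >= floor_abs & peak_val > 0)
  out <- numeric(nrow(A))
  models <- c(double_exp = 0L, mono_exp = 0L, physical_decay_fallback = 0L,
              failed = 0L)
  n_slow <- 0L
  lphys <- if (is.null(half_life_h)) NA_real_ else log(2) / half_life_h
  for (i in sel) {
    tia_i <- tryCatch({
      fit <- fit_decay_double_exp(times, A[i, ], half_life_h = half_life_h)
      models[fit$model] <- models[fit$model] + 1L
      lam_slow <- if (fit$model == "double_exp")
        min(fit$lambda1, fit$lambda2) else fit$lambda1
      if (is.finite(lphys) && lam_slow <= lphys * 1.001)
        n_slow <- n_slow + 1L
      integrate_tac(times, A[i, ], fit, uptake_model = uptake_model)
    }, error = function(e) NA_real_)
    if (is.na(tia_i)) {
      models["failed"] <- models["failed"] + 1L
      tia_i <- 0
    }
    out[i] <- tia_i
  }
  if (models["failed"] > 0)
    warning(models["failed"], " voxel time-activity curves could not be fitted",
            " (set to 0); supply half_life_h to enable the physical-decay",
            " fallback", call. = FALSE)
  if (n_slow > slow_decay_warn_fraction * length(sel) && length(sel) > 0)
    warning(sprintf(
      "effective decay at or below the physical decay constant in %d of %d fitted voxels (floored at the physical rate)",
      n_slow, length(sel)), call. = FALSE)
  res <- new_volume_like(series[[1]], array(pmax(out, 0) * 3600,
                                            dim(series[[1]]$values)),
                         value_kind = "tia_MBq_s",
                         acquisition_time_h = NA_real_)
  attr(res, "model_counts") <- models
  res
}
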
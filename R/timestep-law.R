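# The integrator-induced frequency blue shift of finite-time-step
# molecular dynamics, modelled as a molecule-independent power law in the
# dimensionless frequency x = nu * c * dt:
#
#     delta_x = a * x^b,   delta_x = (nu_D - nu_H) * c * dt
#
# Fitting, forward shift prediction and the inverse correction.

#' Dimensionless frequency
#'
#' `x = nu * c * dt` (non-angular convention): the variable in which the
#' integrator blue shift is molecule-independent.
#'
#' @param nu wavenumber, cm^-1
#' @param dt_fs time step, fs
#' @return unitless x
#' @export
dimensionless_frequency <- function(nu, dt_fs) {
  if (any(dt_fs <= 0)) stop("time step must be positive")
  nu * phys_const$c_cm_fs * dt_fs
}

#' Fit the time-step blue-shift power law
#'
#' Least-squares fit of `log(delta_x)` on `log(x)` over shift points
#' (harmonic frequency, dynamic frequency, time step), giving the
#' constant `a` and exponent `b` of `delta_x = a x^b`. Points with zero
#' or negative shift carry no information about the law and are excluded
#' with a warning.
#'
#' @param nu_h harmonic frequencies, cm^-1
#' @param nu_d dynamic (integrator) frequencies, cm^-1
#' @param dt_fs time step(s), fs (scalar or per point)
#' @return an object of class `shift_law` with components `a`, `b`,
#'   `residual` (RMS log residual), `n_points`
#' @export
fit_shift_law <- function(nu_h, nu_d, dt_fs) {
  if (length(nu_d) != length(nu_h)) stop("nu_h and nu_d lengths differ")
  dt_fs <- rep_len(dt_fs, length(nu_h))
  if (any(dt_fs <= 0)) stop("time steps must be positive")
  x <- dimensionless_frequency(nu_h, dt_fs)
  dx <- dimensionless_frequency(nu_d - nu_h, dt_fs)
  usable <- dx > 0 & x > 0
  if (any(!usable)) {
    warning(sum(!usable), " point(s) with non-positive shift excluded")
  }
  if (sum(usable) < 2L || length(unique(x[usable])) < 2L) {
    stop("need at least 2 usable points with distinct x and positive shift")
  }
  fit <- stats::lm.fit(cbind(1, log(x[usable])), log(dx[usable]))
  a <- exp(fit$coefficients[[1L]])
  b <- fit$coefficients[[2L]]
  structure(list(a = a, b = b,
                 residual = sqrt(mean(fit$residuals^2)),
                 n_points = sum(usable)),
            class = "shift_law")
}

#' Construct a shift law from known constants
#' @param a positive constant
#' @param b exponent (> 1: the shift grows superlinearly)
#' @return a `shift_law`
#' @export
shift_law <- function(a, b) {
  if (a <= 0) stop("constant a must be positive")
  if (b <= 1) stop("exponent b must exceed 1")
  structure(list(a = a, b = b, residual = NA_real_, n_points = 0L),
            class = "shift_law")
}

#' Named shift-law profiles
#'
#' `"admp-b3lyp-n07d"` carries the calibration constants of the
#' extended-Lagrangian DFT propagator (a = 2.95, b = 3.25);
#' `"velocity-verlet"` carries the analytic leading-order law of the
#' velocity-Verlet integrator on a harmonic mode (a = (2 pi)^2 / 24,
#' b = 3, from the Taylor expansion of its closed-form frequency).
#'
#' @param name profile name
#' @return a `shift_law`
#' @export
shift_law_profile <- function(name = c("admp-b3lyp-n07d",
                                       "velocity-verlet")) {
  name <- match.arg(name)
  switch(name,
         "admp-b3lyp-n07d" = shift_law(2.95, 3.25),
         "velocity-verlet" = shift_law((2 * pi)^2 / 24, 3))
}

#' @export
print.shift_law <- function(x, ...) {
  cat(sprintf("Time-step blue-shift power law: delta_x = %.4g * x^%.4g\n",
              x$a, x$b))
  if (x$n_points > 0L) {
    cat(sprintf("  fitted on %d points, RMS log residual %.3g\n",
                x$n_points, x$residual))
  }
  invisible(x)
}

#' @export
coef.shift_law <- function(object, ...) {
  c(a = object$a, b = object$b)
}

#' @export
summary.shift_law <- function(object, ...) {
  cat(sprintf(
    "Power law delta_x = a x^b with a = %.6g, b = %.6g\n", object$a,
    object$b))
  if (object$n_points > 0L) {
    cat(sprintf("Fitted on %d shift points; RMS residual in log space %.3g\n",
                object$n_points, object$residual))
  }
  cat(sprintf(
    "Predicted shift at 1900 cm^-1, dt = 0.5 fs: %.3f cm^-1\n",
    predict_shift(1900, 0.5, object)))
  invisible(object)
}

#' Predicted blue shift at a harmonic frequency
#'
#' `delta_nu = a (nu_H c dt)^b / (c dt)` in cm^-1; monotone increasing in
#' `nu_H` since b > 1.
#'
#' @param nu_h harmonic frequency, cm^-1
#' @param dt_fs time step, fs
#' @param law a `shift_law`
#' @return shift in cm^-1
#' @export
predict_shift <- function(nu_h, dt_fs, law) {
  cdt <- phys_const$c_cm_fs * dt_fs
  law$a * (nu_h * cdt)^law$b / cdt
}

#' @export
predict.shift_law <- function(object, nu_h, dt_fs, ...) {
  predict_shift(nu_h, dt_fs, object)
}

#' Correct a dynamic frequency for the time-step blue shift
#'
#' Solves `nu_H + predict_shift(nu_H) = nu_D` for `nu_H` by Newton
#' iteration (tolerance 1e-8 cm^-1): the inverse of the forward shift, so
#' a spectrum run at a long time step can be mapped back to the
#' zero-time-step frequency axis.
#'
#' @param nu_d dynamic frequency (or vector), cm^-1
#' @param dt_fs time step, fs
#' @param law a `shift_law`
#' @param tol convergence tolerance, cm^-1
#' @param max_iter maximum Newton iterations
#' @return corrected harmonic frequency(ies), cm^-1
#' @export
correct_frequency <- function(nu_d, dt_fs, law, tol = 1e-8,
                              max_iter = 100L) {
  cdt <- phys_const$c_cm_fs * dt_fs
  vapply(nu_d, function(nd) {
    if (nd == 0) return(0)
    nh <- nd
    for (it in seq_len(max_iter)) {
      f <- nh + law$a * (nh * cdt)^law$b / cdt - nd
      fp <- 1 + law$a * law$b * (nh * cdt)^(law$b - 1)
      step <- f / fp
      nh <- nh - step
      if (abs(step) < tol) return(nh)
    }
    stop("Newton iteration did not converge for nu_d = ", nd)
  }, numeric(1))
}

#' Temperature at which classical dynamics matches a mode's quantum width
#'
#' The classical thermal energy equals the vibrational quantum when
#' `k_B T = h c nu`, i.e. `T = c2 * nu` with the second radiation
#' constant c2 = 1.4388 K cm. At 1000 cm^-1 this gives ~1439 K -- the
#' temperature scale needed for a classical trajectory distribution to be
#' as wide as the quantum ground-state density, far above what a floppy
#' peptide survives.
#'
#' @param nu wavenumber, cm^-1
#' @return temperature in K
#' @export
width_match_temperature <- function(nu) {
  if (any(nu < 0)) stop("frequency must be non-negative")
  phys_const$c2_cm_K * nu
}
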
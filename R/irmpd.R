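# IR cross-sections from IRMPD-VUV ion counts.
#
# Idealised model: during the IR macropulse each ground-state molecule is
# excited with rate Phi*sigma, so the surviving (intact) fraction after
# exposure is exp(-Phi*sigma*tau). The VUV pulse then ionises parents and
# fragments with equal total probability; an IR-independent share of the
# parent ions dissociates during/after ionisation. Measuring parent (P)
# and summed-fragment (F) counts with the IR on and off gives
#
#   sigma = [ ln(P_off / (P_off + F_off)) - ln(P_on / (P_on + F_on)) ]
#           / (Phi tau)
#
# where the off-term cancels the nu-independent post-ionisation
# fragmentation.

#' IR cross-section from one ion-count record
#'
#' @param p_on,f_on,p_off,f_off ion counts (parent / summed fragments,
#'   IR on / off)
#' @param phi_tau macropulse photon fluence measure (> 0)
#' @return sigma in reciprocal fluence units; negative values are
#'   possible for noise below baseline and are deliberately not clamped
#'   (clamping would bias the noise statistics)
#' @export
cross_section_point <- function(p_on, f_on, p_off, f_off, phi_tau) {
  if (any(phi_tau <= 0)) stop("phi_tau must be positive")
  if (any(p_on == 0)) {
    stop("infinite depletion: no parent ions detected with IR on")
  }
  if (any(p_off == 0)) {
    stop("no parent ions detected with IR off; off-term undefined")
  }
  if (any(p_on + f_on <= 0) || any(p_off + f_off <= 0)) {
    stop("zero total ion count")
  }
  (log(p_off / (p_off + f_off)) - log(p_on / (p_on + f_on))) / phi_tau
}

#' Macropulse fluence measure from pulse energy
#'
#' The photon fluence is proportional to the number of photons in the
#' macropulse, i.e. to `energy / (h c nu)`; in the arbitrary units used
#' here, `Phi tau = constant * energy_mJ / nu`.
#'
#' @param pulse_energy_mJ macropulse energy, mJ (>= 0)
#' @param nu IR frequency, cm^-1 (> 0)
#' @param constant proportionality constant (default 1)
#' @return fluence measure in arbitrary units
#' @export
fluence <- function(pulse_energy_mJ, nu, constant = 1) {
  if (any(pulse_energy_mJ < 0)) stop("pulse energy must be non-negative")
  if (any(nu <= 0)) stop("frequency must be positive")
  constant * pulse_energy_mJ / nu
}

#' IR action spectrum from a table of ion counts
#'
#' Applies [cross_section_point()] per record and orders by frequency.
#' Records sharing a frequency are averaged with a warning. Points where
#' sigma comes out negative (noise below baseline) are flagged, not
#' clamped. Optionally interpolates onto a uniform grid.
#'
#' @param records an `ion_counts` data.frame
#' @param grid optional uniform frequency grid to interpolate onto; if
#'   given, an [ir_spectrum()] is returned instead
#' @return data.frame of class `action_spectrum` with columns `nu`,
#'   `sigma`, `negative` -- or an `ir_spectrum` when `grid` is supplied
#' @export
build_action_spectrum <- function(records, grid = NULL) {
  if (nrow(records) < 1L) stop("no ion-count records")
  sig <- cross_section_point(records$p_on, records$f_on, records$p_off,
                             records$f_off, records$phi_tau)
  d <- data.frame(nu = records$nu, sigma = sig)
  if (anyDuplicated(d$nu)) {
    warning("duplicate frequencies averaged")
    d <- stats::aggregate(sigma ~ nu, data = d, FUN = mean)
  }
  d <- d[order(d$nu), , drop = FALSE]
  rownames(d) <- NULL
  d$negative <- d$sigma < 0
  class(d) <- c("action_spectrum", "data.frame")
  if (!is.null(grid)) {
    if (nrow(d) < 2L) stop("need >= 2 distinct frequencies to interpolate")
    y <- stats::approx(d$nu, d$sigma, xout = grid, rule = 2)$y
    return(ir_spectrum(grid, y, provenance = "IRMPD action spectrum"))
  }
  d
}

#' @export
print.action_spectrum <- function(x, ...) {
  cat(sprintf("IRMPD action spectrum: %d points, %g - %g cm^-1",
              nrow(x), min(x$nu), max(x$nu)))
  if (any(x$negative)) {
    cat(sprintf(" (%d below baseline)", sum(x$negative)))
  }
  cat("\n")
  invisible(x)
}
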
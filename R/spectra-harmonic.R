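# Broadened IR spectra from harmonic stick spectra: empirical frequency
# scaling, instrument-width Gaussian broadening, Boltzmann-weighted
# composites and a similarity score.

#' Construct a continuous spectrum on a uniform frequency grid
#' @param frequency strictly increasing, uniformly spaced grid, cm^-1
#' @param absorbance values on the grid (finite)
#' @param provenance free-text tag recording how the spectrum was made
#' @return an object of class `ir_spectrum`
#' @export
ir_spectrum <- function(frequency, absorbance, provenance = "") {
  frequency <- as.numeric(frequency); absorbance <- as.numeric(absorbance)
  if (length(frequency) != length(absorbance)) {
    stop("frequency and absorbance must have equal length")
  }
  if (length(frequency) >= 2L) {
    df <- diff(frequency)
    if (any(df <= 0)) stop("frequency grid must be strictly increasing")
    if (max(df) - min(df) > 1e-6 * stats::median(df)) {
      stop("frequency grid must be uniform")
    }
  }
  if (!all(is.finite(absorbance))) stop("absorbance values must be finite")
  structure(list(frequency = frequency, absorbance = absorbance,
                 provenance = provenance),
            class = "ir_spectrum")
}

#' @export
print.ir_spectrum <- function(x, ...) {
  cat(sprintf("IR spectrum: %d points, %g - %g cm^-1",
              length(x$frequency), min(x$frequency), max(x$frequency)))
  if (nzchar(x$provenance)) cat(" [", x$provenance, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Default frequency grid
#'
#' 0.5 cm^-1 spacing over 300-1900 cm^-1, covering the experimental
#' 340-1820 cm^-1 window with margin.
#'
#' @param from,to,by grid limits and spacing, cm^-1
#' @return numeric vector
#' @export
default_grid <- function(from = 300, to = 1900, by = 0.5) {
  seq(from, to, by = by)
}

#' Scale the band frequencies of a stick spectrum
#'
#' Calculated harmonic frequencies are multiplied by an empirical factor
#' (0.98, specific to B3LYP) to correct the systematic overestimate;
#' intensities are unchanged.
#'
#' @param s a `stick_spectrum`
#' @param factor positive scaling factor
#' @return a `stick_spectrum`
#' @export
scale_frequencies <- function(s, factor = 0.98) {
  if (factor <= 0) stop("scaling factor must be positive")
  stick_spectrum(s$frequency * factor, s$intensity)
}

#' Broaden a stick spectrum to a continuous curve
#'
#' Each band (nu, I) becomes a Gaussian with mean nu, standard deviation
#' `width_fraction * nu` (matching the free-electron-laser line width,
#' sigma = 0.01 nu) and integrated area I. The grid must cover every band
#' to +/- 5 sigma so the trapezoid integral of each Gaussian retains its
#' band intensity to 0.1%.
#'
#' @param s a `stick_spectrum`
#' @param width_fraction sigma as a fraction of the band frequency
#' @param grid frequency grid (uniform, cm^-1)
#' @return an `ir_spectrum`
#' @export
broaden <- function(s, width_fraction = 0.01, grid = default_grid()) {
  if (length(s$frequency) > 0L) {
    sig <- width_fraction * s$frequency
    lo <- s$frequency - 5 * sig
    hi <- s$frequency + 5 * sig
    live <- s$intensity > 0
    if (any(live & (lo < min(grid) | hi > max(grid)))) {
      stop("grid does not cover all bands to +/- 5 sigma")
    }
  }
  y <- numeric(length(grid))
  for (b in seq_along(s$frequency)) {
    if (s$intensity[b] == 0) next
    sb <- width_fraction * s$frequency[b]
    y <- y + s$intensity[b] / (sb * sqrt(2 * pi)) *
      exp(-0.5 * ((grid - s$frequency[b]) / sb)^2)
  }
  ir_spectrum(grid, y, provenance = "broadened harmonic")
}

#' Weighted composite of spectra on a common grid
#'
#' Pointwise weighted sum, typically with Boltzmann abundances as weights.
#'
#' @param spectra list of `ir_spectrum` objects on identical grids
#' @param weights numeric weights (abundances), same length
#' @return an `ir_spectrum`
#' @export
composite <- function(spectra, weights) {
  if (length(spectra) == 0L) stop("no spectra to combine")
  if (length(spectra) != length(weights)) {
    stop("one weight per spectrum required")
  }
  f0 <- spectra[[1L]]$frequency
  for (sp in spectra[-1L]) {
    if (length(sp$frequency) != length(f0) ||
        max(abs(sp$frequency - f0)) > 1e-9) {
      stop("spectra are not on a common grid")
    }
  }
  y <- Reduce(`+`, Map(function(sp, w) w * sp$absorbance, spectra,
                       as.list(weights)))
  ir_spectrum(f0, y, provenance = "composite")
}

#' Similarity of two spectra
#'
#' Cosine similarity of the mean-subtracted absorbance vectors (the
#' Pearson correlation of the two curves), in [-1, 1].
#'
#' @param a,b `ir_spectrum` objects on a common grid
#' @return unitless similarity
#' @export
similarity <- function(a, b) {
  if (length(a$frequency) != length(b$frequency) ||
      max(abs(a$frequency - b$frequency)) > 1e-9) {
    stop("spectra are not on a common grid")
  }
  xa <- a$absorbance - mean(a$absorbance)
  xb <- b$absorbance - mean(b$absorbance)
  na <- sqrt(sum(xa^2)); nb <- sqrt(sum(xb^2))
  if (na == 0 || nb == 0) {
    stop("similarity undefined for a zero-variance spectrum")
  }
  sum(xa * xb) / (na * nb)
}

#' Trapezoid integral of a spectrum
#' @param s an `ir_spectrum`
#' @return numeric integral over the grid
#' @export
spectrum_integral <- function(s) {
  f <- s$frequency; y <- s$absorbance
  sum((y[-1] + y[-length(y)]) / 2 * diff(f))
}

#' Read a two-column continuous spectrum
#' @param path file path
#' @return an `ir_spectrum`
#' @export
read_spectrum <- function(path) {
  d <- read_columns(path, 2L, c("nu", "a"))
  ir_spectrum(d$nu, d$a, provenance = path)
}

#' Write a continuous spectrum as two-column text
#' @param s an `ir_spectrum`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_spectrum <- function(s, path) {
  writeLines(c("# nu_cm-1 absorbance",
               sprintf("%.10g %.10g", s$frequency, s$absorbance)), path)
  invisible(path)
}
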
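# Molecular structures, volumetric grids, dipole trajectories, stick spectra
# and ion-count tables: containers plus readers/writers for the standard
# plain-text formats (XYZ, PDB, Gaussian cube, whitespace/comma columns).

#' Construct a molecular structure
#'
#' The basic container for a molecule: element symbols, Cartesian
#' coordinates in Angstrom, an (initially empty) covalent bond list and
#' optional residue labels.
#'
#' @param elements character vector of element symbols
#' @param coords numeric matrix, n x 3, Angstrom
#' @param bonds two-column integer matrix of atom-index pairs (may be empty)
#' @param residue optional character vector of residue labels, length n
#' @return an object of class `mol_structure`
#' @export
mol_structure <- function(elements, coords, bonds = NULL, residue = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an n x 3 matrix")
  n <- nrow(coords)
  if (length(elements) != n) stop("length(elements) must match nrow(coords)")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  bad <- setdiff(unique(elements), .known_elements)
  if (length(bad) > 0) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(bonds)) {
    bonds <- matrix(integer(0), ncol = 2L)
  } else {
    bonds <- matrix(as.integer(bonds), ncol = 2L)
    if (nrow(bonds) > 0 &&
        (min(bonds) < 1L || max(bonds) > n)) {
      stop("bond list references atom indices outside 1..", n)
    }
  }
  if (!is.null(residue) && length(residue) != n) {
    stop("residue labels must have one entry per atom")
  }
  structure(
    list(elements = as.character(elements), coords = unname(coords),
         bonds = bonds, residue = residue),
    class = "mol_structure"
  )
}

#' @export
print.mol_structure <- function(x, ...) {
  cat("Molecular structure:", length(x$elements), "atoms,",
      nrow(x$bonds), "bonds\n")
  tab <- table(x$elements)
  cat("  composition:",
      paste0(names(tab), tab, collapse = " "), "\n")
  if (!is.null(x$residue)) {
    cat("  residues:", paste(unique(x$residue), collapse = " "), "\n")
  }
  invisible(x)
}

#' Number of atoms in a structure
#' @param s a `mol_structure`
#' @return integer atom count
#' @export
n_atoms <- function(s) length(s$elements)

#' Read a molecular structure from file
#'
#' Supports plain XYZ (element x y z, Angstrom) and PDB (via bio3d).
#' Bonds are left empty; use [perceive_bonds()] afterwards.
#'
#' @param path file path
#' @param format `"xyz"` or `"pdb"`; default guesses from the extension
#' @return a `mol_structure`
#' @export
read_structure <- function(path, format = c("auto", "xyz", "pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("pdb", "ent")) "pdb" else "xyz"
  }
  if (format == "xyz") read_xyz(path) else read_pdb_structure(path)
}

read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L) stop("parse error in ", path, ": empty file")
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L) {
    stop("parse error in ", path, " line 1: expected atom count")
  }
  if (length(lines) < n + 2L) {
    stop("parse error in ", path, ": expected ", n, " atom lines")
  }
  el <- character(n)
  xyz <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    ln <- i + 2L
    tok <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1L]]
    if (length(tok) < 4L) {
      stop("parse error in ", path, " line ", ln,
           ": expected 'element x y z'")
    }
    el[i] <- tok[1L]
    v <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(v)) {
      stop("parse error in ", path, " line ", ln,
           ": non-numeric coordinate")
    }
    xyz[i, ] <- v
  }
  mol_structure(el, xyz)
}

#' Write a molecular structure to an XYZ file
#' @param s a `mol_structure`
#' @param path output file path
#' @param comment comment line (line 2 of the file)
#' @return `path`, invisibly
#' @export
write_xyz <- function(s, path, comment = "") {
  n <- n_atoms(s)
  lines <- c(
    as.character(n), comment,
    sprintf("%-2s %14.8f %14.8f %14.8f",
            s$elements, s$coords[, 1], s$coords[, 2], s$coords[, 3])
  )
  writeLines(lines, path)
  invisible(path)
}

read_pdb_structure <- function(path) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  el <- at$elesy
  # fall back to first letter of the atom name when the element column is
  # blank (minimal hand-written PDBs)
  blank <- is.na(el) | trimws(el) == ""
  if (any(blank)) el[blank] <- substr(gsub("[0-9]", "", at$elety[blank]), 1, 1)
  el <- trimws(el)
  el <- paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, 10)))
  mol_structure(el, cbind(at$x, at$y, at$z),
                residue = paste0(at$resid, at$resno))
}

#' Write a molecular structure to a PDB file
#' @param s a `mol_structure`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_pdb_structure <- function(s, path) {
  n <- n_atoms(s)
  if (is.null(s$residue)) {
    resid <- rep("LIG", n); resno <- rep(1L, n)
  } else {
    resid <- substr(s$residue, 1, 3)
    resno <- as.integer(gsub("[^0-9]", "", s$residue))
    resno[is.na(resno)] <- 1L
  }
  # uniquified atom names so round-trips keep atom order unambiguous
  elety <- paste0(s$elements, seq_len(n) %% 100)
  bio3d::write.pdb(file = path, xyz = as.numeric(t(s$coords)),
                   resno = resno, resid = resid, elety = elety,
                   eleno = seq_len(n), elesy = s$elements)
  invisible(path)
}

# ---------------------------------------------------------------------------
# scalar fields (volumetric grids)

#' Construct a scalar field on a regular grid
#'
#' Electron-density-like volumetric data: an origin, three axis step
#' vectors, the grid shape along each axis and the values. Values are held
#' in the canonical density unit nm^-3 (hydrogen-bond thresholds are stated
#' in nm^-3); atomic-unit input is converted on construction.
#'
#' @param origin numeric length 3, Angstrom
#' @param axes 3 x 3 matrix; row i is the step vector of grid axis i (Angstrom)
#' @param shape integer length 3, number of points along each axis
#' @param values numeric array or vector of `prod(shape)` values, ordered with
#'   the third axis fastest (cube-file order)
#' @param unit `"nm^-3"` (default) or `"au"` (electrons/bohr^3; converted)
#' @return an object of class `scalar_field`
#' @export
scalar_field <- function(origin, axes, shape, values, unit = c("nm^-3", "au")) {
  unit <- match.arg(unit)
  axes <- as.matrix(axes)
  shape <- as.integer(shape)
  if (length(origin) != 3L || !all(dim(axes) == c(3L, 3L)) ||
      length(shape) != 3L) {
    stop("origin must be length 3, axes 3x3, shape length 3")
  }
  if (abs(det(axes)) < 1e-12) stop("grid axis vectors must be independent")
  vals <- as.numeric(values)
  if (length(vals) != prod(shape)) {
    stop("value count ", length(vals), " does not match grid shape ",
         paste(shape, collapse = "x"))
  }
  if (unit == "au") vals <- vals * phys_const$au_density_nm3
  structure(
    list(origin = as.numeric(origin), axes = unname(axes), shape = shape,
         values = array(vals, dim = rev(shape))),  # [k, j, i]: axis 3 fastest
    class = "scalar_field"
  )
}

#' @export
print.scalar_field <- function(x, ...) {
  cat("Scalar field:", paste(x$shape, collapse = " x "), "grid,",
      "values in nm^-3, range",
      sprintf("[%.3g, %.3g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Evaluate a scalar field at arbitrary points by trilinear interpolation
#' @param f a `scalar_field`
#' @param points n x 3 matrix of Cartesian points (Angstrom)
#' @return numeric vector; NA outside the grid
#' @export
field_at <- function(f, points) {
  points <- matrix(points, ncol = 3L)
  # fractional grid coordinates: p = origin + t(axes) %*% u
  u <- t(solve(t(f$axes), t(sweep(points, 2L, f$origin))))
  out <- rep(NA_real_, nrow(points))
  for (p in seq_len(nrow(points))) {
    uu <- u[p, ]
    if (any(uu < 0) || any(uu > f$shape - 1L)) next
    i0 <- pmin(floor(uu), f$shape - 2L)
    fr <- uu - i0
    acc <- 0
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      w <- prod(ifelse(c(di, dj, dk) == 1L, fr, 1 - fr))
      acc <- acc + w * f$values[i0[3] + dk + 1L, i0[2] + dj + 1L,
                                i0[1] + di + 1L]
    }
    out[p] <- acc
  }
  out
}

#' Read a Gaussian cube file into a scalar field
#'
#' Standard cube layout: two comment lines, atom-count/origin line, three
#' axis lines, atom block, then values with the z index fastest. Positive
#' atom counts mean Bohr units (converted to Angstrom here).
#'
#' @param path file path
#' @param unit unit of the stored values: `"nm^-3"` (default) or `"au"`
#' @return a `scalar_field`
#' @export
read_density_grid <- function(path, unit = c("nm^-3", "au")) {
  unit <- match.arg(unit)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6L) stop("parse error in ", path, ": truncated cube")
  num <- function(ln) as.numeric(strsplit(trimws(lines[ln]),
                                          "[[:space:]]+")[[1L]])
  l3 <- num(3L)
  natom <- as.integer(l3[1L])
  origin <- l3[2:4]
  axes <- matrix(0, 3, 3); shape <- integer(3)
  for (i in 1:3) {
    li <- num(3L + i)
    shape[i] <- as.integer(li[1L])
    axes[i, ] <- li[2:4]
  }
  # positive voxel counts conventionally flag Bohr lengths, negative Angstrom
  to_A <- phys_const$bohr_A
  if (any(shape < 0L)) { to_A <- 1; shape <- abs(shape) }
  origin <- origin * to_A
  axes <- axes * to_A
  first_val <- 7L + abs(natom)
  vals <- as.numeric(unlist(strsplit(trimws(lines[first_val:length(lines)]),
                                     "[[:space:]]+")))
  vals <- vals[!is.na(vals)]
  scalar_field(origin, axes, shape, vals, unit = unit)
}

#' Write a scalar field as a Gaussian cube file
#' @param f a `scalar_field`
#' @param path output path
#' @param structure optional `mol_structure` to embed as the atom block
#' @return `path`, invisibly
#' @export
write_density_grid <- function(f, path, structure = NULL) {
  b <- phys_const$bohr_A
  natom <- if (is.null(structure)) 0L else n_atoms(structure)
  hdr <- c(
    "scalar field (values nm^-3)", "generated by conformIR",
    sprintf("%5d %12.6f %12.6f %12.6f", natom,
            f$origin[1] / b, f$origin[2] / b, f$origin[3] / b),
    sprintf("%5d %12.6f %12.6f %12.6f", f$shape[1],
            f$axes[1, 1] / b, f$axes[1, 2] / b, f$axes[1, 3] / b),
    sprintf("%5d %12.6f %12.6f %12.6f", f$shape[2],
            f$axes[2, 1] / b, f$axes[2, 2] / b, f$axes[2, 3] / b),
    sprintf("%5d %12.6f %12.6f %12.6f", f$shape[3],
            f$axes[3, 1] / b, f$axes[3, 2] / b, f$axes[3, 3] / b)
  )
  if (!is.null(structure)) {
    z <- match(structure$elements, .known_elements)
    hdr <- c(hdr, sprintf("%5d %12.6f %12.6f %12.6f %12.6f", z, 0,
                          structure$coords[, 1] / b,
                          structure$coords[, 2] / b,
                          structure$coords[, 3] / b))
  }
  # cube order is axis-3 fastest; the [k, j, i] storage flattens to exactly that
  flat <- as.numeric(f$values)
  body <- vapply(split(flat, ceiling(seq_along(flat) / 6)),
                 function(row) paste(sprintf("%13.5e", row), collapse = " "),
                 character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# dipole trajectories

#' Construct a dipole trajectory
#'
#' A uniformly sampled 3-component electric-dipole time series, the raw
#' material for dynamics-based IR spectra.
#'
#' @param dt time step in fs (> 0)
#' @param mu numeric matrix, n x 3, dipole components in Debye
#' @return an object of class `dipole_trajectory` with fields `dt`, `mu`,
#'   `n`, and duration `tau_fs = (n - 1) * dt`
#' @export
dipole_trajectory <- function(dt, mu) {
  mu <- as.matrix(mu)
  if (ncol(mu) != 3L) stop("mu must be an n x 3 matrix")
  if (nrow(mu) < 2L) stop("a dipole trajectory needs at least 2 samples")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("dt must be a positive scalar (fs)")
  }
  structure(
    list(dt = dt, mu = unname(mu), n = nrow(mu),
         tau_fs = (nrow(mu) - 1L) * dt),
    class = "dipole_trajectory"
  )
}

#' @export
print.dipole_trajectory <- function(x, ...) {
  cat(sprintf("Dipole trajectory: %d samples, dt = %g fs, tau = %g ps\n",
              x$n, x$dt, x$tau_fs / 1000))
  invisible(x)
}

#' Read a dipole trajectory from columnar text
#'
#' Expected columns: time (fs), mu_x, mu_y, mu_z (Debye); whitespace or
#' comma separated, `#` comments allowed. Sampling must be uniform: no
#' resampling is attempted because silent interpolation would bias the
#' power spectral density.
#'
#' @param path file path
#' @param tol relative tolerance on time-step uniformity
#' @return a `dipole_trajectory`
#' @export
read_dipole_trajectory <- function(path, tol = 1e-6) {
  d <- read_columns(path, 4L, c("t", "mux", "muy", "muz"))
  dt_all <- diff(d$t)
  if (length(dt_all) < 1L) stop("dipole file has fewer than 2 samples")
  dt <- stats::median(dt_all)
  if (dt <= 0 || any(abs(dt_all - dt) > tol * max(dt, 1e-12))) {
    stop("non-uniform time sampling in ", path,
         " (max deviation ", signif(max(abs(dt_all - dt)), 3), " fs)")
  }
  dipole_trajectory(dt, cbind(d$mux, d$muy, d$muz))
}

#' Write a dipole trajectory as columnar text
#' @param traj a `dipole_trajectory`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_dipole_trajectory <- function(traj, path) {
  t <- (seq_len(traj$n) - 1L) * traj$dt
  writeLines(c("# t_fs mu_x mu_y mu_z",
               sprintf("%.10g %.10g %.10g %.10g",
                       t, traj$mu[, 1], traj$mu[, 2], traj$mu[, 3])),
             path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# stick spectra and ion counts

#' Construct a stick spectrum
#' @param frequency band centres, cm^-1 (> 0)
#' @param intensity integrated band intensities, km/mol (>= 0)
#' @return an object of class `stick_spectrum`
#' @export
stick_spectrum <- function(frequency, intensity) {
  frequency <- as.numeric(frequency); intensity <- as.numeric(intensity)
  if (length(frequency) != length(intensity)) {
    stop("frequency and intensity must have equal length")
  }
  if (any(frequency <= 0)) stop("band frequencies must be positive")
  if (any(intensity < 0)) stop("band intensities must be non-negative")
  structure(list(frequency = frequency, intensity = intensity),
            class = "stick_spectrum")
}

#' @export
print.stick_spectrum <- function(x, ...) {
  cat("Stick spectrum:", length(x$frequency), "bands")
  if (length(x$frequency)) {
    cat(sprintf(", %g - %g cm^-1", min(x$frequency), max(x$frequency)))
  }
  cat("\n")
  invisible(x)
}

#' Read a stick spectrum (frequency, intensity columns)
#' @param path file path
#' @return a `stick_spectrum`
#' @export
read_stick_spectrum <- function(path) {
  d <- read_columns(path, 2L, c("nu", "I"))
  stick_spectrum(d$nu, d$I)
}

#' Write a stick spectrum as two-column text
#' @param s a `stick_spectrum`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_stick_spectrum <- function(s, path) {
  writeLines(c("# nu_cm-1 intensity_km_mol",
               sprintf("%.10g %.10g", s$frequency, s$intensity)), path)
  invisible(path)
}

#' Construct an ion-count table
#'
#' One row per IR frequency point: parent and summed-fragment ion counts
#' with the free-electron-laser macropulse on (`p_on`, `f_on`) and off
#' (`p_off`, `f_off`), plus the macropulse photon fluence measure
#' `phi_tau` (arbitrary units).
#'
#' @param nu IR frequency, cm^-1 (> 0)
#' @param p_on,f_on,p_off,f_off non-negative ion counts
#' @param phi_tau positive fluence measure
#' @return data.frame of class `ion_counts`
#' @export
ion_counts <- function(nu, p_on, f_on, p_off, f_off, phi_tau) {
  d <- data.frame(nu = as.numeric(nu), p_on = as.numeric(p_on),
                  f_on = as.numeric(f_on), p_off = as.numeric(p_off),
                  f_off = as.numeric(f_off), phi_tau = as.numeric(phi_tau))
  if (any(d$nu <= 0)) stop("IR frequencies must be positive")
  if (any(d[, 2:5] < 0)) stop("ion counts must be non-negative")
  if (any(d$p_on + d$f_on <= 0) || any(d$p_off + d$f_off <= 0)) {
    stop("each record needs at least one detected ion on and off")
  }
  if (any(d$phi_tau <= 0)) stop("phi_tau must be positive")
  class(d) <- c("ion_counts", "data.frame")
  d
}

#' Read an ion-count table
#'
#' Columns: nu, p_on, f_on, p_off, f_off, phi_tau.
#' @param path file path
#' @return an `ion_counts` data.frame
#' @export
read_ion_counts <- function(path) {
  d <- read_columns(path, 6L,
                    c("nu", "p_on", "f_on", "p_off", "f_off", "phi_tau"))
  ion_counts(d$nu, d$p_on, d$f_on, d$p_off, d$f_off, d$phi_tau)
}

#' Write an ion-count table
#' @param d an `ion_counts` data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_ion_counts <- function(d, path) {
  writeLines(c("# nu p_on f_on p_off f_off phi_tau",
               do.call(sprintf,
                       c(list("%.10g %.10g %.10g %.10g %.10g %.10g"),
                         unclass(d)[c("nu", "p_on", "f_on", "p_off",
                                      "f_off", "phi_tau")]))), path)
  invisible(path)
}

#' Read a Gibbs-energy table (name, G columns)
#' @param path file path
#' @return data.frame with columns `name` and `gibbs` (kcal/mol)
#' @export
read_gibbs_table <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path, warn = FALSE),
                invert = TRUE, value = TRUE)
  tok <- strsplit(trimws(lines), "[,[:space:]]+")
  name <- vapply(tok, `[`, character(1), 1L)
  g <- suppressWarnings(as.numeric(vapply(tok, `[`, character(1), 2L)))
  if (anyNA(g)) stop("non-numeric Gibbs energy in ", path)
  data.frame(name = name, gibbs = g)
}

# shared columnar reader: whitespace or comma separated, '#' comments
read_columns <- function(path, ncol_min, names) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- grep("^\\s*(#|$)", readLines(path, warn = FALSE),
                invert = TRUE, value = TRUE)
  if (length(lines) == 0L) stop("no data rows in ", path)
  tok <- strsplit(trimws(lines), "[,[:space:]]+")
  nc <- lengths(tok)
  if (any(nc < ncol_min)) {
    stop("parse error in ", path, " line ",
         which(nc < ncol_min)[1L], ": expected ", ncol_min, " columns")
  }
  m <- suppressWarnings(
    vapply(seq_len(ncol_min),
           function(j) as.numeric(vapply(tok, `[`, character(1), j)),
           numeric(length(tok)))
  )
  m <- matrix(m, ncol = ncol_min)
  if (anyNA(m)) stop("non-numeric field in ", path)
  d <- as.data.frame(m)
  names(d) <- names
  d
}
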
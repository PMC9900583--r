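# Velocity-Verlet model dynamics with dipole output: the desk-scale
# stand-in for Born-Oppenheimer MD. Forces come from analytic model
# potentials (site-harmonic wells, pairwise springs, Morse pairs) while
# the simulation protocol -- Maxwell-Boltzmann velocities drawn at twice
# the target temperature so each mode carries kT on average, momentum
# projection, velocity-Verlet integration, dipole recording -- mirrors
# the reference BOMD setup.
#
# Internal mechanical units: amu, Angstrom, fs.

#' Construct a model system
#'
#' @param masses atom masses, amu (> 0)
#' @param coords n x 3 initial coordinates, Angstrom
#' @param charges per-atom charges (e) defining the dipole `mu = sum q r`
#' @param potential potential specification, one of:
#'   `list(type = "site_harmonic", k = <amu/fs^2, scalar or per atom>,
#'   centers = <n x 3>)`;
#'   `list(type = "pair_spring", pairs = <matrix cols i, j, k, r0>)`;
#'   `list(type = "morse", pairs = <matrix cols i, j, D, alpha, r0>)`
#'   (D in amu A^2/fs^2, alpha in 1/A)
#' @return an object of class `model_system`
#' @export
model_system <- function(masses, coords, charges, potential) {
  coords <- matrix(as.numeric(coords), ncol = 3L)
  n <- nrow(coords)
  if (length(masses) != n || any(masses <= 0)) {
    stop("need one positive mass per atom")
  }
  if (length(charges) != n) stop("need one charge per atom")
  if (!is.list(potential) || is.null(potential$type)) {
    stop("potential must be a list with a 'type'")
  }
  if (potential$type == "site_harmonic") {
    potential$k <- rep_len(potential$k, n)
    if (any(potential$k <= 0)) stop("spring constants must be positive")
    if (is.null(potential$centers)) potential$centers <- coords
  } else if (potential$type %in% c("pair_spring", "morse")) {
    p <- potential$pairs <- matrix(potential$pairs,
                                   ncol = if (potential$type == "morse") 5L
                                          else 4L)
    if (any(p[, 3L] <= 0)) stop("potential parameters must be positive")
  } else {
    stop("unknown potential type: ", potential$type)
  }
  structure(list(masses = as.numeric(masses), coords = coords,
                 charges = as.numeric(charges), potential = potential),
            class = "model_system")
}

#' One-dimensional harmonic mode as a model system
#'
#' A single charged atom in a site-harmonic well whose frequency is
#' `nu` cm^-1: `k = m (2 pi c nu)^2`. Displaced along x so that, with
#' zero initial velocity, the dipole is a pure cosine at the
#' integrator's effective frequency.
#'
#' @param nu mode wavenumber, cm^-1
#' @param mass atom mass, amu
#' @param charge atom charge, e
#' @param displacement initial x displacement, Angstrom
#' @return a `model_system`
#' @export
harmonic_mode_system <- function(nu, mass = 1, charge = 1,
                                 displacement = 0.1) {
  omega <- 2 * pi * phys_const$c_cm_fs * nu  # rad/fs
  k <- mass * omega^2
  model_system(masses = mass,
               coords = matrix(c(displacement, 0, 0), 1L),
               charges = charge,
               potential = list(type = "site_harmonic", k = k,
                                centers = matrix(0, 1L, 3L)))
}

# force (n x 3) and potential energy for a model system
model_force <- function(sys, x) {
  p <- sys$potential
  if (p$type == "site_harmonic") {
    dx <- x - p$centers
    list(force = -p$k * dx, energy = sum(p$k * dx^2) / 2)
  } else if (p$type == "pair_spring") {
    f <- matrix(0, nrow(x), 3L); e <- 0
    for (r in seq_len(nrow(p$pairs))) {
      i <- p$pairs[r, 1L]; j <- p$pairs[r, 2L]
      k <- p$pairs[r, 3L]; r0 <- p$pairs[r, 4L]
      d <- x[i, ] - x[j, ]; rij <- sqrt(sum(d^2))
      e <- e + k / 2 * (rij - r0)^2
      fij <- -k * (rij - r0) * d / rij
      f[i, ] <- f[i, ] + fij; f[j, ] <- f[j, ] - fij
    }
    list(force = f, energy = e)
  } else {
    f <- matrix(0, nrow(x), 3L); e <- 0
    for (r in seq_len(nrow(p$pairs))) {
      i <- p$pairs[r, 1L]; j <- p$pairs[r, 2L]
      D <- p$pairs[r, 3L]; al <- p$pairs[r, 4L]; r0 <- p$pairs[r, 5L]
      d <- x[i, ] - x[j, ]; rij <- sqrt(sum(d^2))
      ex <- exp(-al * (rij - r0))
      e <- e + D * (1 - ex)^2
      fij <- -2 * D * al * ex * (1 - ex) * d / rij
      f[i, ] <- f[i, ] + fij; f[j, ] <- f[j, ] - fij
    }
    list(force = f, energy = e)
  }
}

#' Simulation configuration
#' @param dt_fs time step, fs (> 0)
#' @param steps number of integration steps (>= 1)
#' @param temperature target temperature T, K; initial velocities are
#'   drawn at 2T so each mode ends up with average energy kT
#' @param seed RNG seed for the velocity draw
#' @param init `"maxwell"` (Maxwell-Boltzmann at 2T, momenta projected
#'   out) or `"none"` (zero initial velocities)
#' @return list of class `sim_config`
#' @export
sim_config <- function(dt_fs = 0.5, steps = 5000L, temperature = 50,
                       seed = 0L, init = c("maxwell", "none")) {
  init <- match.arg(init)
  if (dt_fs <= 0) stop("time step must be positive")
  if (steps < 1L) stop("need at least one step")
  structure(list(dt_fs = dt_fs, steps = as.integer(steps),
                 temperature = temperature, seed = as.integer(seed),
                 init = init),
            class = "sim_config")
}

#' Draw Maxwell-Boltzmann initial velocities at twice the target temperature
#'
#' Each velocity component is normal with variance `k_B (2T) / m`. After
#' equipartition the ensemble-average energy per vibrational mode is then
#' `k_B T`, since the initial draw puts all of `2 k_B T / 2` per mode
#' into kinetic energy which relaxes half into potential.
#'
#' @param masses atom masses, amu
#' @param temperature target temperature T, K (>= 0)
#' @param seed RNG seed
#' @return n x 3 velocity matrix, Angstrom/fs
#' @export
init_velocities <- function(masses, temperature, seed = 0L) {
  if (temperature < 0) stop("temperature must be non-negative")
  n <- length(masses)
  if (temperature == 0) return(matrix(0, n, 3L))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  sd_v <- sqrt(phys_const$kB_amu_A2_fs2 * 2 * temperature / masses)
  matrix(stats::rnorm(3L * n, sd = rep(sd_v, 3L)), n, 3L)
}

#' Project out total linear and angular momentum
#'
#' Subtracts the centre-of-mass velocity, then the rigid-rotation field
#' `omega x r` with `omega = I^{-1} L` about the centre of mass. For
#' (near-)collinear systems the inertia tensor is inverted by
#' pseudo-inverse, removing angular momentum about the well-defined axes
#' only.
#'
#' @param positions n x 3 coordinates, Angstrom
#' @param velocities n x 3 velocities, Angstrom/fs
#' @param masses atom masses, amu
#' @return n x 3 velocity matrix with zero total linear and angular
#'   momentum (to machine precision about well-defined axes)
#' @export
remove_momenta <- function(positions, velocities, masses) {
  n <- nrow(positions)
  if (n < 1L) stop("need at least one atom")
  m <- masses
  com <- colSums(positions * m) / sum(m)
  r <- sweep(positions, 2L, com)
  v <- sweep(velocities, 2L, colSums(velocities * m) / sum(m))
  if (n == 1L) return(v)
  # angular momentum and inertia tensor about the COM
  L <- colSums(m * t(apply(cbind(r, v), 1L, function(z)
    cross3(z[1:3], z[4:6]))))
  I3 <- matrix(0, 3L, 3L)
  for (i in seq_len(n)) {
    ri <- r[i, ]
    I3 <- I3 + m[i] * (sum(ri^2) * diag(3L) - outer(ri, ri))
  }
  sv <- svd(I3)
  inv_d <- ifelse(sv$d > 1e-10 * max(sv$d), 1 / sv$d, 0)
  omega <- sv$v %*% (inv_d * (t(sv$u) %*% L))
  v - t(apply(r, 1L, function(ri) cross3(as.numeric(omega), ri)))
}

#' Run a velocity-Verlet simulation, recording the dipole
#'
#' Standard velocity-Verlet integration of the model system. The dipole
#' `mu(t) = sum_i q_i r_i(t)` is recorded at every step (in e*Angstrom,
#' reported as-is; only relative spectra matter downstream). Total energy
#' is monitored and a divergence beyond ten times the initial energy
#' aborts with an instability error.
#'
#' @param system a `model_system`
#' @param config a `sim_config`
#' @return a `dipole_trajectory` (`steps + 1` samples, including t = 0)
#'   with attribute `energy` (total energy per recorded step)
#' @export
simulate_md <- function(system, config) {
  dt <- config$dt_fs
  m <- system$masses
  x <- system$coords
  v <- if (config$init == "maxwell") {
    remove_momenta(x, init_velocities(m, config$temperature, config$seed), m)
  } else {
    matrix(0, nrow(x), 3L)
  }
  fe <- model_force(system, x)
  a <- fe$force / m
  nrec <- config$steps + 1L
  mu <- matrix(0, nrec, 3L)
  en <- numeric(nrec)
  ke <- sum(m * v^2) / 2
  mu[1L, ] <- colSums(system$charges * x)
  en[1L] <- ke + fe$energy
  e0 <- en[1L]
  for (s in seq_len(config$steps)) {
    v <- v + 0.5 * dt * a
    x <- x + dt * v
    fe <- model_force(system, x)
    a <- fe$force / m
    v <- v + 0.5 * dt * a
    mu[s + 1L, ] <- colSums(system$charges * x)
    en[s + 1L] <- sum(m * v^2) / 2 + fe$energy
    if (e0 > 0 && en[s + 1L] > 10 * e0) {
      stop("instability: total energy exceeded 10x its initial value at ",
           "step ", s)
    }
  }
  traj <- dipole_trajectory(dt, mu * 4.803205)  # e*A -> Debye
  attr(traj, "energy") <- en
  traj
}

#' Exact velocity-Verlet oscillation frequency of a harmonic mode
#'
#' On a harmonic oscillator of angular frequency `omega = 2 pi c nu`,
#' velocity Verlet produces an exactly periodic position sequence with
#' effective frequency `omega_D = (2 / dt) asin(omega dt / 2)` -- always
#' blue-shifted, by `~ omega^3 dt^2 / 24` at leading order. Requires
#' `omega dt < 2` (the integrator's stability limit).
#'
#' @param nu harmonic wavenumber(s), cm^-1
#' @param dt_fs time step, fs
#' @return effective (dynamic) wavenumber, cm^-1
#' @export
analytic_vv_frequency <- function(nu, dt_fs) {
  omega <- 2 * pi * phys_const$c_cm_fs * nu  # rad/fs
  arg <- omega * dt_fs / 2
  if (any(arg >= 1)) {
    stop("unstable time step: omega * dt / 2 >= 1")
  }
  (2 / dt_fs) * asin(arg) / (2 * pi * phys_const$c_cm_fs)
}
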
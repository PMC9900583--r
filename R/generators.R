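# Synthetic-data generators for every pipeline input: cosine dipole
# signals with known mode content, idealized polyalanine geometries with
# prescribed backbone torsions, analytic density grids with controllable
# hydrogen-bond bridge features, and ion counts drawn from a known
# cross-section curve with IR-independent post-ionization fragmentation.
# All generators are seed-deterministic.

with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a multi-mode cosine dipole signal
#'
#' Sum of cosines at the given wavenumbers plus optional white noise --
#' the standard fixture for testing spectral estimation: the exact mode
#' content is retrievable from the `modes` attribute.
#'
#' @param modes data.frame with columns `nu` (cm^-1), `amplitude`
#'   (Debye) and optionally `phase` (radians)
#' @param dt_fs sampling step, fs
#' @param n number of samples
#' @param noise_sd white-noise standard deviation per component, Debye
#' @param seed RNG seed for the noise
#' @return a `dipole_trajectory` with attribute `modes`
#' @export
gen_dipole_signal <- function(modes, dt_fs, n, noise_sd = 0, seed = 0L) {
  if (is.null(modes$phase)) modes$phase <- rep(0, nrow(modes))
  nyquist <- 1 / (2 * phys_const$c_cm_fs * dt_fs)
  if (any(modes$nu >= nyquist)) {
    stop("mode above the Nyquist frequency ", round(nyquist, 1), " cm^-1")
  }
  t <- (seq_len(n) - 1L) * dt_fs
  mux <- numeric(n)
  for (r in seq_len(nrow(modes))) {
    omega <- 2 * pi * phys_const$c_cm_fs * modes$nu[r]
    mux <- mux + modes$amplitude[r] * cos(omega * t + modes$phase[r])
  }
  mu <- cbind(mux, 0, 0)
  if (noise_sd > 0) {
    mu <- mu + with_seed(seed, matrix(stats::rnorm(3L * n, sd = noise_sd),
                                      n, 3L))
  }
  traj <- dipole_trajectory(dt_fs, mu)
  attr(traj, "modes") <- modes
  traj
}

# NeRF atom placement: the point d with |d - c| = r, angle(d, c, b) =
# theta degrees and dihedral(d, c, b, a) = tor degrees
nerf <- function(a, b, c, r, theta, tor) {
  th <- theta * pi / 180; ph <- tor * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d_local <- c(-r * cos(th), r * sin(th) * cos(ph), r * sin(th) * sin(ph))
  c + d_local[1L] * bc + d_local[2L] * m + d_local[3L] * n
}

# idealized internal-coordinate values (Angstrom, degrees)
.pep_geom <- list(
  n_ca = 1.46, ca_c = 1.52, c_n = 1.33, c_o = 1.23, c_oh = 1.34,
  o_h = 0.97, n_h = 1.01, ca_h = 1.09, ca_cb = 1.52, cb_h = 1.09,
  ang_n_ca_c = 110, ang_ca_c_n = 116, ang_c_n_ca = 122,
  ang_ca_c_o = 121, ang_ca_c_oh = 112, ang_c_o_h = 106,
  ang_c_n_h = 119, ang_cb = 110, ang_hnh = 106
)

#' Generate an idealized polyalanine geometry with prescribed torsions
#'
#' Builds an alanine peptide atom by atom from ideal bond lengths and
#' angles, realising the requested informative backbone torsions
#' (phi_N, psi1, phi2, psi2, ..., psi_C; 2n values for n residues)
#' essentially exactly. Peptide omega angles are fixed trans (180) and
#' side-chain methyls staggered trans. Preset motifs provide torsion
#' values that close the classic pseudo-rings.
#'
#' @param n_residues number of alanine residues (>= 1)
#' @param torsions numeric vector of 2 * n_residues informative angles
#'   (degrees), or NULL to use `motif`
#' @param motif `"extended"` (all trans), `"beta-turn"` (type-I turn at
#'   residues `motif_at`..`motif_at + 3`) or `"gamma-turn"` (classic
#'   gamma at residue `motif_at + 1`)
#' @param motif_at first residue of the motif (for the turn motifs)
#' @return a `mol_structure` with bonds perceived and residue labels set
#' @export
gen_toy_peptide <- function(n_residues = 5L, torsions = NULL,
                            motif = c("extended", "beta-turn",
                                      "gamma-turn"),
                            motif_at = 1L) {
  motif <- match.arg(motif)
  if (n_residues < 1L) stop("need at least one residue")
  if (is.null(torsions)) torsions <- peptide_torsions(n_residues, motif,
                                                      motif_at)
  if (length(torsions) != 2L * n_residues) {
    stop("torsion spec must have ", 2L * n_residues,
         " informative angles for ", n_residues, " residues, got ",
         length(torsions))
  }
  g <- .pep_geom
  # informative angle layout: phi_N, psi1, phi2, psi2, ..., phin, psi_C
  phi <- c(torsions[1L],
           if (n_residues > 1L) torsions[2L * (2:n_residues) - 1L])
  psi <- torsions[2L * (1:n_residues)]
  el <- character(0); xyz <- NULL; lab <- character(0)
  add <- function(e, p, l) {
    el <<- c(el, e); xyz <<- rbind(xyz, p); lab <<- c(lab, l)
    length(el)
  }
  N <- CA <- C <- integer(n_residues)
  # seed triad
  N[1] <- add("N", c(0, 0, 0), "ALA1")
  CA[1] <- add("C", c(g$n_ca, 0, 0), "ALA1")
  ang <- g$ang_n_ca_c * pi / 180
  C[1] <- add("C", c(g$n_ca - g$ca_c * cos(ang), g$ca_c * sin(ang), 0),
              "ALA1")
  for (i in seq_len(n_residues - 1L)) {
    res <- paste0("ALA", i + 1L)
    N[i + 1] <- add("N", nerf(xyz[N[i], ], xyz[CA[i], ], xyz[C[i], ],
                              g$c_n, g$ang_ca_c_n, psi[i]), res)
    CA[i + 1] <- add("C", nerf(xyz[CA[i], ], xyz[C[i], ], xyz[N[i + 1], ],
                               g$n_ca, g$ang_c_n_ca, 180), res)
    C[i + 1] <- add("C", nerf(xyz[C[i], ], xyz[N[i + 1], ], xyz[CA[i + 1], ],
                              g$ca_c, g$ang_n_ca_c, phi[i + 1]), res)
  }
  # carbonyl O and amide H of each peptide unit
  for (i in seq_len(n_residues - 1L)) {
    add("O", nerf(xyz[N[i], ], xyz[CA[i], ], xyz[C[i], ],
                  g$c_o, g$ang_ca_c_o, wrap_angle(psi[i] + 180)),
        paste0("ALA", i))
    add("H", nerf(xyz[CA[i], ], xyz[C[i], ], xyz[N[i + 1], ],
                  g$n_h, g$ang_c_n_h, 0), paste0("ALA", i + 1L))
  }
  # C-terminal COOH: hydroxyl O at psi_C, carbonyl O opposite, H anti
  nn <- n_residues
  res_c <- paste0("ALA", nn)
  o_h <- add("O", nerf(xyz[N[nn], ], xyz[CA[nn], ], xyz[C[nn], ],
                       g$c_oh, g$ang_ca_c_oh, psi[nn]), res_c)
  add("O", nerf(xyz[N[nn], ], xyz[CA[nn], ], xyz[C[nn], ],
                g$c_o, g$ang_ca_c_o, wrap_angle(psi[nn] + 180)), res_c)
  add("H", nerf(xyz[CA[nn], ], xyz[C[nn], ], xyz[o_h, ],
                g$o_h, g$ang_c_o_h, 180), res_c)
  # N-terminal amine: midpoint of the two H realises phi_N exactly
  mdir <- nerf(xyz[C[1], ], xyz[CA[1], ], xyz[N[1], ], 1, 109.5, phi[1])
  e <- mdir - xyz[N[1], ]
  u <- cross3(e, xyz[CA[1], ] - xyz[N[1], ])
  u <- u / sqrt(sum(u^2))
  half <- g$ang_hnh / 2 * pi / 180
  for (sgn in c(1, -1)) {
    add("H", xyz[N[1], ] + g$n_h * (cos(half) * e + sgn * sin(half) * u),
        "ALA1")
  }
  # side chains: CB + methyl H, and the alpha H; torsions about the N-CA
  # axis are referenced to the backbone C so handedness is uniform
  for (i in seq_len(n_residues)) {
    res <- paste0("ALA", i)
    cb <- add("C", nerf(xyz[C[i], ], xyz[N[i], ], xyz[CA[i], ],
                        g$ca_cb, g$ang_cb, 122), res)
    add("H", nerf(xyz[C[i], ], xyz[N[i], ], xyz[CA[i], ],
                  g$ca_h, 108, -119), res)
    for (tor in c(180, 60, -60)) {
      add("H", nerf(xyz[N[i], ], xyz[CA[i], ], xyz[cb, ],
                    g$cb_h, 110, tor), res)
    }
  }
  s <- mol_structure(el, xyz, residue = lab)
  perceive_bonds(s)
}

wrap_angle <- function(a) {
  a <- (a + 180) %% 360 - 180
  ifelse(a == -180, 180, a)
}

#' Preset backbone torsion profiles
#'
#' `"extended"`: all informative angles 180 (a fully extended strand,
#' which names to all-T and closes no pseudo-ring under the geometric
#' hydrogen-bond criteria). `"beta-turn"`: type-I beta-turn angles
#' (-60, -30) / (-90, 0) at residues `at + 1`, `at + 2`, bringing the
#' amide H of residue `at + 3` over the carbonyl O of residue `at`
#' (a C10 ring). `"gamma-turn"`: classic gamma angles (75, -65) at
#' residue `at + 1`, closing a C7 ring between residues `at` and
#' `at + 2`.
#'
#' @param n_residues number of residues
#' @param motif profile name
#' @param at first residue of the motif
#' @return numeric vector of 2 * n_residues informative angles, degrees
#' @export
peptide_torsions <- function(n_residues,
                             motif = c("extended", "beta-turn",
                                       "gamma-turn"),
                             at = 1L) {
  motif <- match.arg(motif)
  ang <- rep(180, 2L * n_residues)
  set_phi <- function(ang, i, v) { ang[2L * i - 1L] <- v; ang }
  set_psi <- function(ang, i, v) { ang[2L * i] <- v; ang }
  if (motif == "beta-turn") {
    if (at + 3L > n_residues) stop("beta-turn motif needs residues ",
                                   at, "..", at + 3L)
    ang <- set_phi(ang, at + 1L, -60); ang <- set_psi(ang, at + 1L, -30)
    ang <- set_phi(ang, at + 2L, -90); ang <- set_psi(ang, at + 2L, 0)
  } else if (motif == "gamma-turn") {
    if (at + 2L > n_residues) stop("gamma-turn motif needs residues ",
                                   at, "..", at + 2L)
    ang <- set_phi(ang, at + 1L, 75); ang <- set_psi(ang, at + 1L, -65)
  }
  ang
}

#' Generate an analytic density grid for a structure
#'
#' Sum of atom-centred Gaussians plus an optional "bridge" Gaussian
#' midway between a donor hydrogen and an acceptor -- a controllable
#' stand-in for the electron-density ridge of a hydrogen bond, letting
#' the NCI classifier be exercised against a known ground truth.
#'
#' @param s a `mol_structure`
#' @param atom_amplitude peak density per atom, nm^-3
#' @param atom_width Gaussian sigma per atom, Angstrom
#' @param bridge NULL, or `list(h = <atom index>, acceptor = <atom index>,
#'   rho = <peak nm^-3>, width = <sigma Angstrom>)`
#' @param spacing grid spacing, Angstrom
#' @param padding margin around the molecule, Angstrom
#' @return a `scalar_field`
#' @export
gen_density_grid <- function(s, atom_amplitude = 300, atom_width = 0.25,
                             bridge = NULL, spacing = 0.2, padding = 2) {
  lo <- apply(s$coords, 2L, min) - padding
  hi <- apply(s$coords, 2L, max) + padding
  shape <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  axes <- diag(3L) * spacing
  idx <- as.matrix(expand.grid(i = seq_len(shape[1]) - 1L,
                               j = seq_len(shape[2]) - 1L,
                               k = seq_len(shape[3]) - 1L))
  pts <- sweep(idx %*% axes, 2L, lo, `+`)
  vals <- numeric(nrow(pts))
  for (at in seq_len(n_atoms(s))) {
    d2 <- rowSums(sweep(pts, 2L, s$coords[at, ])^2)
    vals <- vals + atom_amplitude * exp(-d2 / (2 * atom_width^2))
  }
  if (!is.null(bridge)) {
    mid <- (s$coords[bridge$h, ] + s$coords[bridge$acceptor, ]) / 2
    d2 <- rowSums(sweep(pts, 2L, mid)^2)
    vals <- vals + bridge$rho * exp(-d2 / (2 * bridge$width^2))
  }
  # expand.grid varies i fastest but cube/scalar_field order wants axis 3
  # fastest: reorder to (k fastest within j within i)
  ord <- order(idx[, 1L], idx[, 2L], idx[, 3L])
  scalar_field(lo, axes, shape, vals[ord])
}

#' Generate ion counts from a known cross-section curve
#'
#' The generative twin of the IRMPD detection model: at each frequency,
#' `n` molecules survive the IR pulse with probability
#' `exp(-phi_tau * sigma)`; an IR-independent fraction `frag_fraction`
#' of the ionised parents dissociates after ionisation. Parent counts
#' are binomial, fragments are the remainder.
#'
#' @param nu frequencies, cm^-1
#' @param sigma generating cross-section at each frequency (reciprocal
#'   fluence units)
#' @param phi_tau fluence measure per frequency (scalar or vector)
#' @param frag_fraction IR-independent post-ionisation fragmentation
#'   fraction in `[0, 1)`
#' @param n number of detected molecules per frequency and shutter state
#' @param seed RNG seed
#' @return an `ion_counts` data.frame with attribute `sigma_true`
#' @export
gen_ion_counts <- function(nu, sigma, phi_tau = 1, frag_fraction = 0.1,
                           n = 1e5, seed = 0L) {
  if (frag_fraction < 0 || frag_fraction >= 1) {
    stop("frag_fraction must be in [0, 1)")
  }
  phi_tau <- rep_len(phi_tau, length(nu))
  surv <- exp(-phi_tau * sigma)
  counts <- with_seed(seed, {
    p_on <- stats::rbinom(length(nu), n, surv * (1 - frag_fraction))
    p_off <- stats::rbinom(length(nu), n, 1 - frag_fraction)
    list(p_on = p_on, p_off = p_off)
  })
  d <- ion_counts(nu, counts$p_on, n - counts$p_on, counts$p_off,
                  n - counts$p_off, phi_tau)
  attr(d, "sigma_true") <- sigma
  d
}
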
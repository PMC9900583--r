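# Hydrogen-bond assignment: NCI-style (electron-density grid: density
# threshold, reduced density gradient, sign of the second Hessian
# eigenvalue) and a purely geometric fallback; pseudo-ring orders.

#' Construct a hydrogen-bond record
#' @param donor,h,acceptor atom indices (donor heavy atom, its H, acceptor)
#' @param strength maximum density along the contact, nm^-3 (NA when
#'   assigned geometrically)
#' @param class `"hbond"` or `"weak-interaction"`
#' @return an object of class `hbond`
#' @export
hbond <- function(donor, h, acceptor, strength = NA_real_,
                  class = "hbond") {
  structure(list(donor = as.integer(donor), h = as.integer(h),
                 acceptor = as.integer(acceptor),
                 strength = as.numeric(strength), class = class,
                 ring_order = NA_integer_, ring_path = NULL),
            class = "hbond")
}

#' @export
print.hbond <- function(x, ...) {
  cat(sprintf("%s: donor %d (H %d) -> acceptor %d", x$class, x$donor, x$h,
              x$acceptor))
  if (!is.na(x$strength)) cat(sprintf(", rho_max = %.1f nm^-3", x$strength))
  if (!is.na(x$ring_order)) cat(sprintf(", ring order C%d", x$ring_order))
  cat("\n")
  invisible(x)
}

# candidate donor-H / acceptor pairs from geometry: donor heavy atom is an
# N or O with a bonded H; acceptor is any other N or O not bonded to the H
hbond_candidates <- function(s, d_max = 3.5) {
  adj <- bond_adjacency(s)
  el <- s$elements
  out <- list()
  for (d in which(el %in% c("N", "O"))) {
    hs <- adj[[d]][el[adj[[d]]] == "H"]
    for (h in hs) {
      for (a in which(el %in% c("N", "O"))) {
        if (a == d || a %in% adj[[h]]) next
        r <- sqrt(sum((s$coords[h, ] - s$coords[a, ])^2))
        if (r <= d_max) out[[length(out) + 1L]] <- c(d, h, a, r)
      }
    }
  }
  out
}

#' Geometric hydrogen-bond detection
#'
#' Fallback used when no electron-density grid is available: a donor
#' H...acceptor contact is a hydrogen bond iff the H...A distance is at
#' most `d_max` and the donor-H...A angle is at least `theta_min`
#' (common literature cutoffs). Strength is left undefined.
#'
#' @param s a `mol_structure` with bonds perceived
#' @param d_max maximum H...acceptor distance, Angstrom
#' @param theta_min minimum donor-H...acceptor angle, degrees
#' @return list of `hbond` objects
#' @export
detect_hbonds_geometric <- function(s, d_max = 2.5, theta_min = 120) {
  cands <- hbond_candidates(s, d_max = d_max)
  out <- list()
  for (cd in cands) {
    d <- cd[1L]; h <- cd[2L]; a <- cd[3L]
    v1 <- s$coords[d, ] - s$coords[h, ]
    v2 <- s$coords[a, ] - s$coords[h, ]
    ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                               sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
    if (ang >= theta_min) out[[length(out) + 1L]] <- hbond(d, h, a)
  }
  out
}

# gradient and Hessian of a scalar field at grid node (i, j, k) by central
# finite differences (one grid spacing), in Cartesian Angstrom coordinates
field_derivatives <- function(f, idx) {
  i <- idx[1L]; j <- idx[2L]; k <- idx[3L]
  sh <- f$shape
  if (any(idx < 2L) || any(idx > sh - 1L)) return(NULL)  # needs interior
  v <- function(ii, jj, kk) f$values[kk, jj, ii]
  g_frac <- c((v(i + 1, j, k) - v(i - 1, j, k)) / 2,
              (v(i, j + 1, k) - v(i, j - 1, k)) / 2,
              (v(i, j, k + 1) - v(i, j, k - 1)) / 2)
  h_frac <- matrix(0, 3, 3)
  v0 <- v(i, j, k)
  h_frac[1, 1] <- v(i + 1, j, k) - 2 * v0 + v(i - 1, j, k)
  h_frac[2, 2] <- v(i, j + 1, k) - 2 * v0 + v(i, j - 1, k)
  h_frac[3, 3] <- v(i, j, k + 1) - 2 * v0 + v(i, j, k - 1)
  h_frac[1, 2] <- h_frac[2, 1] <-
    (v(i + 1, j + 1, k) - v(i + 1, j - 1, k) -
     v(i - 1, j + 1, k) + v(i - 1, j - 1, k)) / 4
  h_frac[1, 3] <- h_frac[3, 1] <-
    (v(i + 1, j, k + 1) - v(i + 1, j, k - 1) -
     v(i - 1, j, k + 1) + v(i - 1, j, k - 1)) / 4
  h_frac[2, 3] <- h_frac[3, 2] <-
    (v(i, j + 1, k + 1) - v(i, j + 1, k - 1) -
     v(i, j - 1, k + 1) + v(i, j - 1, k - 1)) / 4
  ainv <- solve(f$axes)        # fractional step -> Cartesian: x = t(A) u
  grad <- as.numeric(ainv %*% g_frac)
  hess <- ainv %*% h_frac %*% t(ainv)
  list(value = v0, grad = grad, hess = (hess + t(hess)) / 2)
}

# reduced density gradient s(rho, grad rho), evaluated in atomic units
reduced_gradient <- function(rho_nm3, grad_nm3_A) {
  rho_au <- rho_nm3 / phys_const$au_density_nm3
  gnorm_au <- sqrt(sum(grad_nm3_A^2)) / phys_const$au_density_nm3 *
    phys_const$bohr_A
  if (rho_au <= 0) return(Inf)
  gnorm_au / (2 * (3 * pi^2)^(1 / 3) * rho_au^(4 / 3))
}

#' NCI hydrogen-bond detection on an electron-density grid
#'
#' A candidate donor-H...acceptor pair is labelled a hydrogen bond iff at
#' some grid point in the corridor between the H and the acceptor all
#' three conditions hold: density `rho >= rho_hbond` (default 18 nm^-3),
#' reduced density gradient `s <= s_max`, and second Hessian eigenvalue
#' `lambda_2 <= 0`. The same test with `rho_weak <= rho < rho_hbond`
#' (default 15-18 nm^-3) labels a weak interaction. The reported strength
#' is the maximum density over qualifying points. Derivatives are taken by
#' central finite differences with a one-grid-spacing step.
#'
#' @param s a `mol_structure` with bonds perceived
#' @param field a `scalar_field` holding the density (nm^-3)
#' @param rho_hbond,rho_weak density thresholds, nm^-3
#' @param s_max reduced-density-gradient cutoff (unitless)
#' @param corridor_radius half-width of the H...acceptor corridor, Angstrom
#' @param d_max maximum H...acceptor distance for candidate pairs, Angstrom
#' @param t_range fraction of the H->acceptor segment examined; the
#'   default excludes the 20% nearest each nucleus, where the density is
#'   nuclear rather than interactional
#' @return list of `hbond` objects
#' @export
detect_hbonds_nci <- function(s, field, rho_hbond = 18, rho_weak = 15,
                              s_max = 0.5, corridor_radius = 0.5,
                              d_max = 3.5, t_range = c(0.2, 0.8)) {
  cands <- hbond_candidates(s, d_max = d_max)
  out <- list()
  sh <- field$shape
  # Cartesian coordinates of all grid nodes, once
  idx <- as.matrix(expand.grid(i = seq_len(sh[1]), j = seq_len(sh[2]),
                               k = seq_len(sh[3])))
  nodes <- sweep((idx - 1) %*% field$axes, 2L, field$origin, `+`)
  for (cd in cands) {
    h <- cd[2L]; a <- cd[3L]
    p0 <- s$coords[h, ]; p1 <- s$coords[a, ]
    seg <- p1 - p0; L2 <- sum(seg^2)
    t_par <- as.numeric(sweep(nodes, 2L, p0) %*% seg) / L2
    inside <- t_par >= t_range[1L] & t_par <= t_range[2L]
    perp2 <- rowSums((nodes - (outer(t_par, seg) +
                                 rep(p0, each = nrow(nodes))))^2)
    sel <- which(inside & perp2 <= corridor_radius^2)
    if (length(sel) == 0L) {
      stop("density grid does not cover the H...acceptor corridor for ",
           "atoms ", h, " -> ", a)
    }
    best <- -Inf
    for (m in sel) {
      der <- field_derivatives(field, idx[m, ])
      if (is.null(der)) next
      if (der$value < rho_weak) next
      if (reduced_gradient(der$value, der$grad) > s_max) next
      if (sort(eigen(der$hess, symmetric = TRUE,
                     only.values = TRUE)$values)[2L] > 0) next
      best <- max(best, der$value)
    }
    if (is.finite(best)) {
      cls <- if (best >= rho_hbond) "hbond" else "weak-interaction"
      out[[length(out) + 1L]] <- hbond(cd[1L], h, a, strength = best,
                                       class = cls)
    }
  }
  out
}

#' Pseudo-ring order of a hydrogen bond
#'
#' The number of atoms on the shortest covalent path from the donor
#' hydrogen to the acceptor, inclusive of both: the size of the ring the
#' H...acceptor contact closes. A C10 ring is a beta-turn (residues i and
#' i+3), C7 a gamma-turn (i and i+2), and C5 the intra-unit NH...O
#' contact. Undefined (NA) for intermolecular contacts.
#'
#' @param hb an `hbond`
#' @param s the `mol_structure` (bonds perceived)
#' @return integer ring order, or NA when no covalent path exists
#' @export
ring_order <- function(hb, s) {
  path <- covalent_path(s, hb$h, hb$acceptor)
  if (is.null(path)) NA_integer_ else length(path)
}

#' Attach ring orders and ring paths to a list of hydrogen bonds
#' @param hbonds list of `hbond` objects
#' @param s the `mol_structure`
#' @return the list with `ring_order` and `ring_path` fields filled in
#' @export
assign_rings <- function(hbonds, s) {
  lapply(hbonds, function(hb) {
    path <- covalent_path(s, hb$h, hb$acceptor)
    if (!is.null(path)) {
      hb$ring_order <- length(path)
      hb$ring_path <- path
    }
    hb
  })
}

#' Turn type implied by a pseudo-ring order
#' @param order integer ring order(s)
#' @return character: `"beta-turn"` (C10), `"gamma-turn"` (C7), `"C5"`, or NA
#' @export
turn_type <- function(order) {
  ifelse(order == 10L, "beta-turn",
         ifelse(order == 7L, "gamma-turn",
                ifelse(order == 5L, "C5", NA_character_)))
}
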
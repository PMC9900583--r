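# Dihedral geometry, torsion extraction, angle classification and the
# descriptive conformer-naming scheme.

#' Signed dihedral angle of four points
#'
#' IUPAC sign convention: looking from p2 towards p3, a clockwise rotation
#' of the far bond relative to the near bond is positive. The value lies in
#' (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric length-3 points (Angstrom)
#' @return signed angle in degrees
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10) {
    stop("degenerate geometry: three consecutive points are collinear")
  }
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2) / sqrt(sum(b2^2))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Classify a torsion angle as cis/gauche/anticlinal/trans
#'
#' Symmetric 60-degree sectors by absolute value: cis (C) for |theta| < 30,
#' gauche (G) for 30 <= |theta| < 90, anticlinal (A) for 90 <= |theta| < 150
#' and trans (T) for |theta| >= 150.
#'
#' @param theta angle(s) in degrees, in (-180, 180]
#' @return character vector of single letters C/G/A/T
#' @export
classify_angle <- function(theta) {
  if (any(theta <= -180 | theta > 180)) {
    stop("angles must lie in (-180, 180]")
  }
  a <- abs(theta)
  ifelse(a < 30, "C", ifelse(a < 90, "G", ifelse(a < 150, "A", "T")))
}

#' Backbone torsion angles of an annotated peptide
#'
#' Computes the informative torsions of a free peptide: the terminal
#' `phi_N` (defined by extending the backbone to the centre of the amino
#' group, i.e. the midpoint of the two amine hydrogens), the interior
#' phi/psi pairs, and the terminal `psi_C` (to the hydroxyl O of the
#' COOH). The omega (peptide bond) and chi (side chain) angles are
#' retained as metadata. For n residues there are 2n informative angles.
#'
#' @param s a `mol_structure` with bonds perceived
#' @param bb its `backbone_annotation`
#' @return an object of class `torsion_set`: list with `angles` (named
#'   numeric: phi_N, psi1, phi2, psi2, ..., psi_C), `omega`, `chi`
#' @export
compute_torsions <- function(s, bb) {
  xyz <- s$coords
  res <- bb$residues
  n <- nrow(res)
  p <- function(i) xyz[i, ]
  ang <- numeric(0)
  # phi_N: midpoint of amine hydrogens -> N -> CA -> C
  hm <- colMeans(xyz[bb$nterm$H, , drop = FALSE])
  ang["phi_N"] <- dihedral(hm, p(res$N[1]), p(res$CA[1]), p(res$C[1]))
  for (i in seq_len(n)) {
    if (i > 1L) {
      ang[paste0("phi", i)] <-
        dihedral(p(res$C[i - 1]), p(res$N[i]), p(res$CA[i]), p(res$C[i]))
    }
    if (i < n) {
      ang[paste0("psi", i)] <-
        dihedral(p(res$N[i]), p(res$CA[i]), p(res$C[i]), p(res$N[i + 1]))
    }
  }
  ang["psi_C"] <- dihedral(p(res$N[n]), p(res$CA[n]), p(res$C[n]),
                           p(bb$cterm$O_hydroxyl))
  # reorder: phi_N, psi1, phi2, psi2, ..., phin, psi_C
  ord <- c("phi_N", "psi1")
  if (n > 1L) {
    for (i in 2:n) {
      ord <- c(ord, paste0("phi", i),
               if (i < n) paste0("psi", i))
    }
  }
  ord <- c(ord, "psi_C")
  ang <- ang[ord[ord %in% names(ang)]]
  omega <- numeric(0)
  for (i in seq_len(n - 1L)) {
    omega[paste0("omega", i)] <-
      dihedral(p(res$CA[i]), p(res$C[i]), p(res$N[i + 1]), p(res$CA[i + 1]))
  }
  chi <- numeric(0)
  for (i in seq_len(n)) {
    if (!is.na(res$CB[i])) {
      chi[paste0("chi", i)] <-
        dihedral(p(res$N[i]), p(res$CA[i]), p(res$CB[i]), p(res$C[i]))
    }
  }
  structure(list(angles = ang, omega = omega, chi = chi, n_residues = n),
            class = "torsion_set")
}

#' @export
print.torsion_set <- function(x, ...) {
  cat("Torsion set (", x$n_residues, " residues):\n", sep = "")
  print(round(x$angles, 1))
  invisible(x)
}

# map from informative-angle position (1..2n) to the rotatable backbone
# bond it turns about, as a sorted atom-index pair
torsion_bonds <- function(bb) {
  res <- bb$residues
  n <- nrow(res)
  bonds <- list()
  bonds[[1L]] <- sort(c(res$N[1], res$CA[1]))        # phi_N
  k <- 2L
  for (i in seq_len(n)) {
    if (i > 1L) {
      bonds[[k]] <- sort(c(res$N[i], res$CA[i])); k <- k + 1L  # phi_i
    }
    bonds[[k]] <- sort(c(res$CA[i], res$C[i])); k <- k + 1L    # psi_i / psi_C
  }
  bonds
}

#' Descriptive conformer name from torsions and hydrogen bonds
#'
#' Each informative torsion (N-terminus leftmost) is classified as
#' C/G/A/T and the letters concatenated. Where a detected hydrogen bond
#' closes a pseudo-ring -- a C10 beta-turn, C7 gamma-turn or C5 ring --
#' the letters of exactly those torsions whose rotatable bond lies on the
#' covalent ring path are replaced by one bracketed token `[b]`, `[g]`
#' or `[C5]`.
#'
#' @param torsions a `torsion_set` (or plain numeric vector of angles)
#' @param hbonds list of `hbond` objects (may be empty); each must carry a
#'   `ring_order` and `ring_path` (atom indices) as produced by
#'   [ring_order()] via [assign_rings()]
#' @param bb the `backbone_annotation` (needed to map torsions to bonds;
#'   may be omitted when `hbonds` is empty)
#' @return a single string
#' @export
descriptive_name <- function(torsions, hbonds = list(), bb = NULL) {
  ang <- if (inherits(torsions, "torsion_set")) torsions$angles
         else as.numeric(torsions)
  n_res <- if (inherits(torsions, "torsion_set")) torsions$n_residues
           else length(ang) / 2
  if (length(ang) != 2 * n_res) {
    stop("expected ", 2 * n_res, " informative angles, got ", length(ang))
  }
  letters_out <- as.list(classify_angle(ang))
  if (length(hbonds) > 0L) {
    if (is.null(bb)) stop("backbone annotation required to place turn tokens")
    tb <- torsion_bonds(bb)
    for (hb in hbonds) {
      ro <- hb$ring_order
      if (is.null(ro) || is.na(ro)) next
      token <- if (ro == 10L) "[b]" else if (ro == 7L) "[g]"
               else if (ro == 5L) "[C5]" else next
      path <- hb$ring_path
      path_bonds <- lapply(seq_len(length(path) - 1L),
                           function(j) sort(path[j:(j + 1L)]))
      covered <- vapply(tb, function(b)
        any(vapply(path_bonds, function(pb) all(pb == b), logical(1))),
        logical(1))
      if (!any(covered)) next
      idx <- which(covered)
      letters_out[idx] <- ""
      letters_out[[min(idx)]] <- token
    }
  }
  paste0(unlist(letters_out), collapse = "")
}
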
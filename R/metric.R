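# Conformer distance: root-sum-square atom displacement (RSSAD) and its
# minimum over proper rigid motions and symmetry-equivalent atom
# reindexings (MRSSAD).

#' Root-sum-square atom displacement for a fixed correspondence
#'
#' `sqrt(sum_i ||x_i - y_i||^2)`; equals RMSD times sqrt(N). No alignment
#' is performed. All atoms carry equal weight.
#'
#' @param a,b `mol_structure` objects (or n x 3 coordinate matrices) with
#'   equal atom counts
#' @return distance in Angstrom
#' @export
rssad <- function(a, b) {
  xa <- if (inherits(a, "mol_structure")) a$coords else as.matrix(a)
  xb <- if (inherits(b, "mol_structure")) b$coords else as.matrix(b)
  if (nrow(xa) != nrow(xb)) stop("atom counts differ")
  if (inherits(a, "mol_structure") && inherits(b, "mol_structure") &&
      !identical(sort(a$elements), sort(b$elements))) {
    stop("element multisets differ")
  }
  sqrt(sum((xa - xb)^2))
}

# optimal proper superposition of x onto y (Kabsch, equal weights,
# reflections excluded so enantiomers stay at non-zero distance)
kabsch <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2L, cx); yc <- sweep(y, 2L, cy)
  sv <- svd(crossprod(xc, yc))
  d <- sign(det(sv$u) * det(sv$v))
  s <- diag(c(1, 1, d))
  r <- sv$u %*% s %*% t(sv$v)
  sweep(xc %*% r, 2L, cy, `+`)
}

#' Symmetry-equivalent atom orbits of a structure
#'
#' Partitions the atoms into classes that a covalent-graph automorphism
#' (refined by element) could permute, by iterative neighbourhood-signature
#' refinement: start from element labels and repeatedly relabel each atom
#' by the multiset of its neighbours' labels until stable. Reindexing in
#' [mrssad()] is restricted to these orbits; the full permutation space is
#' both chemically wrong and intractable.
#'
#' @param s a `mol_structure` with bonds perceived
#' @return integer vector of orbit ids, one per atom
#' @export
atom_orbits <- function(s) {
  adj <- bond_adjacency(s)
  lab <- match(s$elements, unique(s$elements))
  repeat {
    sig <- vapply(seq_along(lab), function(i) {
      paste(lab[i], paste(sort(lab[adj[[i]]]), collapse = ","), sep = "|")
    }, character(1))
    new_lab <- match(sig, unique(sig))
    if (identical(new_lab, lab)) break
    lab <- new_lab
  }
  lab
}

# minimum-cost perfect assignment on a square cost matrix; exhaustive for
# small sizes, igraph maximum-weight bipartite matching otherwise
solve_assignment <- function(cost) {
  n <- nrow(cost)
  if (n == 1L) return(1L)
  if (n <= 6L) {
    perms <- permutations_of(n)
    costs <- vapply(seq_len(nrow(perms)), function(r) {
      sum(cost[cbind(seq_len(n), perms[r, ])])
    }, numeric(1))
    return(perms[which.min(costs), ])
  }
  w <- max(cost) - cost + 1
  edges <- as.vector(t(cbind(rep(seq_len(n), each = n),
                             n + rep(seq_len(n), times = n))))
  g <- igraph::make_bipartite_graph(rep(c(FALSE, TRUE), each = n), edges)
  m <- igraph::max_bipartite_match(g, weights = as.vector(t(w)))
  as.integer(m$matching[seq_len(n)]) - n
}

# all permutations of 1..n as rows (n <= 7 in practice)
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- seq_len(nrow(sub)) + r
    out[rows, 1L] <- k
    remap <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(remap[sub], nrow(sub))
    r <- r + nrow(sub)
  }
  out
}

#' Minimal root-sum-square atom displacement (MRSSAD)
#'
#' The minimum of [rssad()] over proper rigid motions (rotations and
#' translations; reflections excluded so that enantiomers of a chiral
#' molecule do not collapse to zero) and over atom reindexings within
#' symmetry-equivalent orbits. Computed by alternating optimal
#' superposition (Kabsch) with optimal within-orbit assignment until a
#' fixed point, taking the best over several random orbit-respecting
#' starting permutations. The result is a metric: zero iff the conformers
#' are congruent, symmetric, and obeying the triangle inequality.
#'
#' @param a,b `mol_structure` objects with equal element multisets
#' @param orbits integer orbit ids per atom (common to both structures,
#'   in `a`'s atom order); default computed from `a`'s covalent graph
#' @param n_starts number of random initial permutations (plus identity)
#' @param seed RNG seed for the random starts
#' @return list of class `mrssad_result`: `distance` (Angstrom),
#'   `permutation` (index into `b` for each atom of `a`)
#' @export
mrssad <- function(a, b, orbits = NULL, n_starts = 10, seed = 0) {
  xa <- a$coords; xb <- b$coords
  if (nrow(xa) != nrow(xb)) stop("atom counts differ")
  if (!identical(sort(a$elements), sort(b$elements))) {
    stop("element multisets differ")
  }
  n <- nrow(xa)
  if (is.null(orbits)) {
    orbits <- if (nrow(a$bonds) > 0L) atom_orbits(a)
              else match(a$elements, unique(a$elements))
  }
  if (length(orbits) != n) stop("orbit partition length mismatch")
  for (o in unique(orbits)) {
    if (length(unique(a$elements[orbits == o])) != 1L) {
      stop("orbit partition mixes elements")
    }
  }
  orbit_idx <- split(seq_len(n), orbits)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  starts <- c(list(seq_len(n)), lapply(seq_len(max(0L, n_starts - 1L)),
    function(...) {
      p <- seq_len(n)
      for (ix in orbit_idx) p[ix] <- ix[sample.int(length(ix))]
      p
    }))
  best <- Inf; best_perm <- seq_len(n)
  for (perm in starts) {
    repeat {
      yb <- xb[perm, , drop = FALSE]
      xa_fit <- kabsch(xa, yb)
      # reassign within orbits given the current superposition
      new_perm <- perm
      for (ix in orbit_idx) {
        if (length(ix) == 1L) next
        cost <- outer(seq_along(ix), seq_along(ix),
                      Vectorize(function(p, q) {
                        sum((xa_fit[ix[p], ] - xb[perm[ix[q]], ])^2)
                      }))
        asg <- solve_assignment(cost)
        new_perm[ix] <- perm[ix][asg]
      }
      d_new <- rssad(kabsch(xa, xb[new_perm, , drop = FALSE]),
                     xb[new_perm, , drop = FALSE])
      d_old <- rssad(xa_fit, yb)
      if (d_new < d_old - 1e-12) { perm <- new_perm } else break
    }
    d <- rssad(kabsch(xa, xb[perm, , drop = FALSE]),
               xb[perm, , drop = FALSE])
    if (d < best) { best <- d; best_perm <- perm }
  }
  structure(list(distance = best, permutation = best_perm),
            class = "mrssad_result")
}

#' @export
print.mrssad_result <- function(x, ...) {
  cat(sprintf("MRSSAD = %.4f A\n", x$distance))
  invisible(x)
}

#' Pairwise MRSSAD distance matrix for a conformer set
#' @param records a `conformer_set` whose structures are populated
#' @param ... passed to [mrssad()]
#' @return symmetric numeric matrix (Angstrom) with zero diagonal
#' @export
pairwise_mrssad <- function(records, ...) {
  m <- n_conformers(records)
  d <- matrix(0, m, m)
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      d[i, j] <- d[j, i] <-
        mrssad(records$structures[[i]], records$structures[[j]], ...)$distance
    }
  }
  rownames(d) <- colnames(d) <- records$short_name
  d
}
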
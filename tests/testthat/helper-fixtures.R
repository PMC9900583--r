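# Fixture builders shared across the suite. Everything is generated in
# code; nothing is read from disk except files the tests write themselves.

# water in XYZ text form
water_xyz_text <- function() {
  c("3", "water",
    "O   0.000000   0.000000   0.117300",
    "H   0.000000   0.757200  -0.469200",
    "H   0.000000  -0.757200  -0.469200")
}

# benzene: ideal hexagon, C-C 1.39 A, C-H 1.09 A
benzene <- function() {
  th <- (0:5) * pi / 3
  cc <- cbind(1.39 * cos(th), 1.39 * sin(th), 0)
  ch <- cbind(2.48 * cos(th), 2.48 * sin(th), 0)
  perceive_bonds(mol_structure(rep(c("C", "H"), each = 6), rbind(cc, ch)))
}

# minimal N-H...O triad for hydrogen-bond fixtures (H...O distance ~2 A)
nho_triad <- function(d_ho = 1.99) {
  perceive_bonds(mol_structure(
    c("N", "H", "O"),
    rbind(c(0, 0, 0), c(1.01, 0, 0), c(1.01 + d_ho, 0, 0))))
}

# apply a random proper rotation + translation (seeded)
rigid_motion <- function(coords, seed = 1) {
  set.seed(seed)
  a <- stats::rnorm(3)
  # Rodrigues rotation about a random axis by a random angle
  ax <- a / sqrt(sum(a^2))
  th <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(coords %*% t(R), 2L, stats::rnorm(3, sd = 3), `+`)
}

# small random structure with a repeated element (one non-trivial orbit)
random_small_structure <- function(seed, n_equiv = 3L, n_unique = 3L) {
  set.seed(seed)
  el <- c(rep("H", n_equiv), c("C", "N", "O", "F", "S")[seq_len(n_unique)])
  mol_structure(el, matrix(stats::rnorm(3 * length(el), sd = 1.5),
                           ncol = 3L))
}

# exhaustive MRSSAD oracle: minimum over ALL orbit-respecting
# permutations, each with optimal proper superposition
mrssad_bruteforce <- function(a, b, orbits) {
  n <- nrow(a$coords)
  orbit_idx <- split(seq_len(n), orbits)
  perm_sets <- lapply(orbit_idx, function(ix) {
    if (length(ix) == 1L) return(matrix(ix, 1L))
    p <- conformIR:::permutations_of(length(ix))
    matrix(ix[p], nrow(p))
  })
  combos <- Reduce(function(acc, ps) {
    out <- NULL
    for (r1 in seq_len(nrow(acc))) {
      for (r2 in seq_len(nrow(ps))) {
        out <- rbind(out, c(acc[r1, ], ps[r2, ]))
      }
    }
    out
  }, perm_sets[-1L], accumulate = FALSE, init = perm_sets[[1L]])
  cols <- unlist(orbit_idx)
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    perm <- integer(n)
    perm[cols] <- combos[r, ]
    yb <- b$coords[perm, , drop = FALSE]
    xa <- conformIR:::kabsch(a$coords, yb)
    best <- min(best, sqrt(sum((xa - yb)^2)))
  }
  best
}
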
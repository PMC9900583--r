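# RSSAD/MRSSAD conformer distances and the threshold graph with its
# minimal spanning forest.

test_that("rssad matches the Pythagorean closed forms", {
  a <- mol_structure(c("C", "C"), rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_equal(rssad(a, a), 0)
  b <- a; b$coords[1, ] <- c(0, 3, 0)
  expect_equal(rssad(a, b), 3)
  b$coords[2, ] <- c(1, 0, 4)
  expect_equal(rssad(a, b), 5)
  expect_error(rssad(a$coords, matrix(0, 3, 3)), "atom counts differ")
})

test_that("mrssad is zero for rigid copies and symmetry-permuted copies", {
  s <- gen_toy_peptide(2)
  s2 <- s; s2$coords <- rigid_motion(s$coords, seed = 5)
  expect_lt(mrssad(s, s2)$distance, 1e-8)
  # cyclically permute one methyl's hydrogens: zero with reindexing,
  # positive without
  adj <- conformIR:::bond_adjacency(s)
  cb <- which(s$elements == "C" &
                vapply(seq_along(s$elements), function(i)
                  sum(s$elements[adj[[i]]] == "H") == 3L, logical(1)))[1]
  hs <- adj[[cb]][s$elements[adj[[cb]]] == "H"]
  s3 <- s; s3$coords[hs, ] <- s$coords[c(hs[2], hs[3], hs[1]), ]
  expect_lt(mrssad(s, s3)$distance, 1e-8)
  expect_gt(rssad(s, s3), 1)
})

test_that("reflections are excluded: enantiomers stay apart", {
  s <- gen_toy_peptide(2, torsions = c(150, -60, 75, -65))
  s2 <- s; s2$coords[, 3] <- -s2$coords[, 3]
  s2 <- perceive_bonds(s2)
  expect_gt(mrssad(s, s2)$distance, 0.5)
})

test_that("mrssad equals the exhaustive oracle on small instances", {
  for (seed in 1:8) {
    a <- random_small_structure(seed, n_equiv = 3L, n_unique = 3L)
    b <- random_small_structure(seed + 100, n_equiv = 3L, n_unique = 3L)
    orbits <- match(a$elements, unique(a$elements))
    got <- mrssad(a, b, orbits = orbits)$distance
    want <- mrssad_bruteforce(a, b, orbits)
    expect_equal(got, want, tolerance = 1e-8)
  }
  # 4-atom toy with 2 equivalent atoms
  a <- random_small_structure(50, n_equiv = 2L, n_unique = 2L)
  b <- random_small_structure(51, n_equiv = 2L, n_unique = 2L)
  orbits <- match(a$elements, unique(a$elements))
  expect_equal(mrssad(a, b, orbits = orbits)$distance,
               mrssad_bruteforce(a, b, orbits), tolerance = 1e-8)
})

test_that("mrssad is a metric on sampled triples and bounded by rssad", {
  set.seed(77)
  n_triples <- 25
  structs <- lapply(1:(3 * n_triples), function(i)
    random_small_structure(i, n_equiv = 2L, n_unique = 3L))
  orbits <- match(structs[[1]]$elements, unique(structs[[1]]$elements))
  d <- function(x, y) mrssad(x, y, orbits = orbits, n_starts = 5)$distance
  for (t in seq_len(n_triples)) {
    a <- structs[[3 * t - 2]]; b <- structs[[3 * t - 1]]
    c <- structs[[3 * t]]
    dab <- d(a, b); dbc <- d(b, c); dac <- d(a, c)
    expect_equal(d(a, a), 0, tolerance = 1e-8)
    expect_equal(dab, d(b, a), tolerance = 1e-6)
    expect_lte(dac, dab + dbc + 1e-8)
    expect_lte(dab, rssad(a, b) + 1e-8)
  }
})

test_that("mrssad is invariant to rigid motion of either argument", {
  a <- random_small_structure(7)
  b <- random_small_structure(8)
  orbits <- match(a$elements, unique(a$elements))
  d0 <- mrssad(a, b, orbits = orbits)$distance
  b2 <- b; b2$coords <- rigid_motion(b$coords, seed = 2)
  a2 <- a; a2$coords <- rigid_motion(a$coords, seed = 3)
  expect_equal(mrssad(a, b2, orbits = orbits)$distance, d0,
               tolerance = 1e-6)
  expect_equal(mrssad(a2, b, orbits = orbits)$distance, d0,
               tolerance = 1e-6)
})

test_that("atom orbits separate elements and respect topology", {
  s <- gen_toy_peptide(2)
  orb <- atom_orbits(s)
  # orbits never mix elements
  for (o in unique(orb)) {
    expect_length(unique(s$elements[orb == o]), 1L)
  }
  # methyl hydrogens form orbits of three
  sizes <- table(orb)
  expect_gte(sum(sizes == 3), 2L)
})

test_that("threshold graphs connect exactly the close pairs", {
  d <- matrix(c(0, 5, 5, 5, 0, 5, 5, 5, 0), 3, 3)
  g <- build_graph(c("A1", "A2", "A3"), d)
  expect_equal(nrow(g$edges), 3L)
  g2 <- build_graph(c("A1", "A2", "A3"), d * 3)
  expect_equal(nrow(g2$edges), 0L)
  # mixed distances: edge set matches per-pair comparison
  set.seed(12)
  m <- matrix(runif(36, 2, 18), 6, 6); m <- (m + t(m)) / 2; diag(m) <- 0
  g3 <- build_graph(paste0("A", 1:6), m)
  want <- sum(m[upper.tri(m)] < 10)
  expect_equal(nrow(g3$edges), want)
  expect_error(build_graph(c("A1", "A2"), matrix(c(0, 1, 2, 0), 2, 2)),
               "symmetric")
})

test_that("the spanning forest is minimal and deterministic", {
  # triangle with weights 1, 2, 3 keeps the 1 and 2 edges
  d <- matrix(0, 3, 3)
  d[1, 2] <- d[2, 1] <- 1; d[2, 3] <- d[3, 2] <- 2; d[1, 3] <- d[3, 1] <- 3
  g <- build_graph(c("A1", "A2", "A3"), d)
  kept <- g$edges[g$edges$in_forest, c("from", "to")]
  expect_equal(sort(g$edges$weight[g$edges$in_forest]), c(1, 2))
  # path graph: every edge kept
  dp <- matrix(99, 4, 4); diag(dp) <- 0
  dp[1, 2] <- dp[2, 1] <- 1; dp[2, 3] <- dp[3, 2] <- 1
  dp[3, 4] <- dp[4, 3] <- 1
  gp <- build_graph(paste0("A", 1:4), dp, threshold = 10)
  expect_true(all(gp$edges$in_forest))
  # two disconnected pairs: both pair edges kept
  dd <- matrix(99, 4, 4); diag(dd) <- 0
  dd[1, 2] <- dd[2, 1] <- 2; dd[3, 4] <- dd[4, 3] <- 3
  gd <- build_graph(paste0("A", 1:4), dd)
  expect_equal(sum(gd$edges$in_forest), 2L)
})

test_that("the spanning forest weight matches igraph's MST", {
  set.seed(31)
  m <- matrix(runif(100, 1, 15), 10, 10); m <- (m + t(m)) / 2; diag(m) <- 0
  g <- build_graph(paste0("A", 1:10), m)
  ours <- sum(g$edges$weight[g$edges$in_forest])
  ig <- as_igraph(g)
  theirs <- sum(igraph::E(igraph::mst(ig, weights =
                                        igraph::E(ig)$weight))$weight)
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("pairwise distance matrices feed the graph end to end", {
  confs <- list(gen_toy_peptide(2),
                gen_toy_peptide(2, torsions = c(150, -60, 75, -65)),
                gen_toy_peptide(2, torsions = c(60, 60, -120, 100)))
  cs <- rank_and_weight(conformer_set(confs, gibbs = c(0, 1, 2)))
  dm <- pairwise_mrssad(cs, n_starts = 4)
  expect_true(isSymmetric(dm))
  expect_true(all(diag(dm) == 0))
  g <- build_graph(cs, dm, threshold = 10)
  expect_identical(g$nodes$name, cs$short_name)
  expect_equal(sum(g$nodes$abundance), 1)
})
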
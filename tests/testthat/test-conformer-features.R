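# Torsions, angle classification, hydrogen bonds, pseudo-rings,
# descriptive names and Boltzmann abundances.

test_that("dihedral matches hand-evaluated cases and the IUPAC sign", {
  expect_equal(dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 0)), 0)
  expect_equal(dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(-1, 1, 0)),
               180)
  expect_equal(dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(0, 1, 1)),
               -90)
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("angle classification uses the symmetric C/G/A/T sectors", {
  expect_identical(classify_angle(10), "C")
  expect_identical(classify_angle(180), "T")
  expect_identical(classify_angle(-100), "A")
  expect_identical(classify_angle(c(-29.9, 30, 89.9, 90, 149.9, 150)),
                   c("C", "G", "G", "A", "A", "T"))
  expect_error(classify_angle(-180), "in \\(-180, 180\\]")
})

test_that("angle classification is even and total over (-180, 180]", {
  th <- seq(-179.5, 180, by = 0.5)
  lab <- classify_angle(th)
  expect_true(all(lab %in% c("C", "G", "A", "T")))
  expect_identical(classify_angle(-th[th < 180]), classify_angle(th[th < 180]))
})

test_that("generated peptides realise their torsion spec to 1 degree", {
  spec <- c(150, -60, 75, -65, 180, 45, -90, 120, 60, -170)
  s <- gen_toy_peptide(5, torsions = spec)
  ts <- compute_torsions(s, annotate_backbone(s))
  expect_equal(unname(ts$angles), spec, tolerance = 0.5)
  expect_equal(unname(ts$omega), rep(180, 4), tolerance = 1e-6)
})

test_that("torsion spec of the wrong length is rejected", {
  expect_error(gen_toy_peptide(2, torsions = rep(180, 10)), "4 informative")
  expect_no_error(descriptive_name(rep(180, 8), list()))
  # a torsion_set disagreeing with its own residue count errors
  ts <- structure(list(angles = rep(180, 8), n_residues = 5L),
                  class = "torsion_set")
  expect_error(descriptive_name(ts), "expected 10 informative angles")
})

test_that("geometric hydrogen-bond criteria: distance and angle cutoffs", {
  expect_length(detect_hbonds_geometric(nho_triad(1.99)), 1L)
  expect_length(detect_hbonds_geometric(nho_triad(3.5)), 0L)
  # 2.0 A but 90-degree donor-H...acceptor angle: below the angular cutoff
  s <- perceive_bonds(mol_structure(
    c("N", "H", "O"), rbind(c(0, 0, 0), c(1.01, 0, 0), c(1.01, 2, 0))))
  expect_length(detect_hbonds_geometric(s), 0L)
})

test_that("NCI classifier grades bridge densities into hbond classes", {
  s <- nho_triad()
  grid_for <- function(rho) gen_density_grid(
    s, bridge = list(h = 2, acceptor = 3, rho = rho, width = 0.35))
  strong <- detect_hbonds_nci(s, grid_for(25))
  expect_length(strong, 1L)
  expect_identical(strong[[1]]$class, "hbond")
  expect_equal(strong[[1]]$strength, 25, tolerance = 0.02)
  weak <- detect_hbonds_nci(s, grid_for(16))
  expect_identical(weak[[1]]$class, "weak-interaction")
  expect_length(detect_hbonds_nci(s, gen_density_grid(s)), 0L)
})

test_that("NCI detection reports uncovered corridors", {
  s <- nho_triad()
  f <- gen_density_grid(s, padding = 2)
  f$origin <- f$origin + 50  # move the grid away from the molecule
  expect_error(detect_hbonds_nci(s, f), "corridor")
})

test_that("NCI and geometric detectors agree on the bridged triad", {
  s <- nho_triad()
  f <- gen_density_grid(s, bridge = list(h = 2, acceptor = 3, rho = 25,
                                         width = 0.35))
  nci <- detect_hbonds_nci(s, f)
  geo <- detect_hbonds_geometric(s)
  pair <- function(h) c(h$donor, h$h, h$acceptor)
  expect_identical(lapply(nci, pair), lapply(geo, pair))
})

test_that("ring orders are 5, 7 and 10 for C5, gamma- and beta-turns", {
  # beta-turn: amide H of residue i+3 to carbonyl O of residue i -> C10
  s <- gen_toy_peptide(5, motif = "beta-turn")
  hb <- assign_rings(detect_hbonds_geometric(s), s)
  expect_length(hb, 1L)
  expect_identical(hb[[1]]$ring_order, 10L)
  expect_identical(turn_type(hb[[1]]$ring_order), "beta-turn")
  # gamma-turn -> C7
  s <- gen_toy_peptide(5, motif = "gamma-turn")
  hb <- assign_rings(detect_hbonds_geometric(s), s)
  expect_identical(hb[[1]]$ring_order, 7L)
  # C5: intra-unit N-H...O=C
  s <- gen_toy_peptide(5)
  bb <- annotate_backbone(s)
  hb <- assign_rings(list(hbond(bb$residues$N[1], bb$nterm$H[1],
                                bb$residues$O[1])), s)
  expect_identical(hb[[1]]$ring_order, 5L)
  expect_identical(ring_order(hb[[1]], s), 5L)
})

test_that("ring order is invariant under rigid motion and reindexing", {
  s <- gen_toy_peptide(5, motif = "gamma-turn")
  hb0 <- assign_rings(detect_hbonds_geometric(s), s)[[1]]
  s2 <- s; s2$coords <- rigid_motion(s$coords, seed = 11)
  s2 <- perceive_bonds(s2)
  hb2 <- assign_rings(detect_hbonds_geometric(s2), s2)[[1]]
  expect_identical(hb2$ring_order, hb0$ring_order)
  # reindex atoms by a random permutation
  set.seed(3)
  perm <- sample.int(n_atoms(s))
  inv <- order(perm)
  s3 <- mol_structure(s$elements[perm], s$coords[perm, ])
  s3 <- perceive_bonds(s3)
  hb3 <- hbond(inv[hb0$donor], inv[hb0$h], inv[hb0$acceptor])
  expect_identical(ring_order(hb3, s3), hb0$ring_order)
})

test_that("descriptive names replace exactly the ring-path torsions", {
  s <- gen_toy_peptide(5)
  bb <- annotate_backbone(s)
  ts <- compute_torsions(s, bb)
  expect_identical(descriptive_name(ts), "TTTTTTTTTT")
  # gamma-turn at residues 1-3 replaces phi2, psi2 (positions 3-4)
  sg <- gen_toy_peptide(5, motif = "gamma-turn")
  bbg <- annotate_backbone(sg)
  hbg <- assign_rings(detect_hbonds_geometric(sg), sg)
  expect_identical(descriptive_name(compute_torsions(sg, bbg), hbg, bbg),
                   "TT[g]TTTTTT")
  # beta-turn replaces the four torsions inside the C10 ring
  sb <- gen_toy_peptide(5, motif = "beta-turn")
  bbb <- annotate_backbone(sb)
  hbb <- assign_rings(detect_hbonds_geometric(sb), sb)
  expect_identical(descriptive_name(compute_torsions(sb, bbb), hbb, bbb),
                   "TT[b]TTTT")
  # C5 at the N-terminus covers phi_N and psi1
  hb5 <- assign_rings(list(hbond(bb$residues$N[1], bb$nterm$H[1],
                                 bb$residues$O[1])), s)
  expect_identical(descriptive_name(ts, hb5, bb), "[C5]TTTTTTTT")
})

test_that("Boltzmann abundances hit the closed forms", {
  # equal energies -> 50/50
  cs <- rank_and_weight(conformer_set(gibbs = c(1, 1)))
  expect_equal(cs$abundance, c(0.5, 0.5))
  # delta G = RT ln 2 at 400 K -> 2/3, 1/3
  dg <- phys_const$kB_kcal_mol * 400 * log(2)
  cs <- rank_and_weight(conformer_set(gibbs = c(0, dg)), temperature = 400)
  expect_equal(cs$abundance, c(2 / 3, 1 / 3), tolerance = 1e-9)
  expect_identical(cs$short_name, c("A1", "A2"))
  expect_identical(cs$rank, c(1L, 2L))
  # delta G -> infinity: all weight on the lowest
  cs <- rank_and_weight(conformer_set(gibbs = c(0, 1e6)))
  expect_equal(cs$abundance, c(1, 0))
  expect_error(rank_and_weight(conformer_set(gibbs = numeric(0))),
               "at least one")
})

test_that("abundances sum to 1 and are invariant to an energy offset", {
  set.seed(21)
  for (rep in 1:5) {
    g <- runif(8, 0, 6)
    a1 <- rank_and_weight(conformer_set(gibbs = g))$abundance
    a2 <- rank_and_weight(conformer_set(gibbs = g + 123.4))$abundance
    expect_equal(sum(a1), 1)
    expect_equal(a1, a2, tolerance = 1e-9)
  }
})
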
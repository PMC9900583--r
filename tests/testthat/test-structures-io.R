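# Structure, grid, trajectory and table IO; bond perception; backbone
# annotation.

test_that("XYZ round-trip preserves elements and coordinates", {
  p <- withr::local_tempfile(fileext = ".xyz")
  writeLines(water_xyz_text(), p)
  s <- read_structure(p)
  expect_equal(s$elements, c("O", "H", "H"))
  expect_equal(nrow(s$coords), 3L)
  p2 <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(s, p2)
  s2 <- read_structure(p2, format = "xyz")
  expect_equal(s2$coords, s$coords, tolerance = 1e-4)
  expect_identical(s2$elements, s$elements)
})

test_that("PDB round-trip preserves residue labels and coordinates", {
  s <- gen_toy_peptide(2)
  p <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_structure(s, p)
  s2 <- read_structure(p)
  expect_identical(s2$elements, s$elements)
  expect_identical(unique(s2$residue), c("ALA1", "ALA2"))
  expect_lt(max(abs(s2$coords - s$coords)), 1e-2)
})

test_that("unknown element symbols are rejected", {
  p <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "", "Xx 0 0 0"), p)
  expect_error(read_structure(p), "unknown element")
  expect_error(mol_structure("Zz", matrix(0, 1, 3)), "unknown element")
})

test_that("malformed XYZ files name the offending line", {
  p <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "", "O 0 0 0", "H 0 zero 0"), p)
  expect_error(read_structure(p), "line 4")
})

test_that("bond perception follows the covalent-radius criterion", {
  h2 <- perceive_bonds(mol_structure(c("H", "H"),
                                     rbind(c(0, 0, 0), c(0.74, 0, 0))))
  expect_equal(nrow(h2$bonds), 1L)
  he2 <- perceive_bonds(mol_structure(c("He", "He"),
                                      rbind(c(0, 0, 0), c(10, 0, 0))))
  expect_equal(nrow(he2$bonds), 0L)
  expect_error(
    perceive_bonds(mol_structure(c("C", "C"),
                                 rbind(c(0, 0, 0), c(0.2, 0, 0)))),
    "overlapping")
})

test_that("perceived bonds match a hand-built list on a dipeptide and are
          invariant under rigid motion", {
  s <- gen_toy_peptide(2)
  bb <- annotate_backbone(s)
  # the peptide link C1-N2 must be present
  expect_true(any(apply(s$bonds, 1L, function(b)
    setequal(b, c(bb$residues$C[1], bb$residues$N[2])))))
  # every bond joins atoms within the scaled covalent-radius sum
  r <- covalent_radius(s$elements)
  d <- as.matrix(dist(s$coords))
  for (k in seq_len(nrow(s$bonds))) {
    i <- s$bonds[k, 1]; j <- s$bonds[k, 2]
    expect_lte(d[i, j], 1.15 * (r[i] + r[j]))
  }
  s2 <- s; s2$coords <- rigid_motion(s$coords, seed = 4)
  s2 <- perceive_bonds(s2)
  expect_identical(s2$bonds, s$bonds)
})

test_that("backbone annotation finds residues and termini", {
  for (nres in c(2L, 5L)) {
    s <- gen_toy_peptide(nres)
    bb <- annotate_backbone(s)
    expect_equal(n_residues(bb), nres)
    expect_length(bb$nterm$H, 2L)
    expect_identical(s$elements[bb$cterm$H_hydroxyl], "H")
    expect_identical(s$elements[bb$cterm$O_hydroxyl], "O")
    # consecutive residues joined by a peptide C-N bond
    for (i in seq_len(nres - 1L)) {
      expect_true(any(apply(s$bonds, 1L, function(b)
        setequal(b, c(bb$residues$C[i], bb$residues$N[i + 1])))))
    }
  }
})

test_that("non-peptides are rejected by the backbone annotator", {
  expect_error(annotate_backbone(benzene()), "not a free peptide")
})

test_that("cube-format grids round-trip", {
  set.seed(9)
  f <- scalar_field(origin = c(-1, -2, 0.5), axes = diag(3) * 0.4,
                    shape = c(4, 5, 6), values = runif(120, 0, 30))
  p <- withr::local_tempfile(fileext = ".cube")
  write_density_grid(f, p)
  f2 <- read_density_grid(p)
  expect_equal(f2$origin, f$origin, tolerance = 1e-5)
  expect_equal(f2$axes, f$axes, tolerance = 1e-5)
  expect_identical(f2$shape, f$shape)
  expect_equal(f2$values, f$values, tolerance = 1e-4)
})

test_that("atomic-unit densities are converted to nm^-3", {
  f <- scalar_field(c(0, 0, 0), diag(3), c(2, 2, 2), rep(1, 8),
                    unit = "au")
  expect_equal(unique(as.numeric(f$values)), 6748.33)
})

test_that("dipole trajectories round-trip and reject jittered sampling", {
  tr <- gen_dipole_signal(data.frame(nu = 900, amplitude = 1),
                          dt_fs = 1, n = 128)
  p <- withr::local_tempfile(fileext = ".dat")
  write_dipole_trajectory(tr, p)
  tr2 <- read_dipole_trajectory(p)
  expect_equal(tr2$dt, tr$dt)
  expect_equal(tr2$mu, tr$mu, tolerance = 1e-8)
  # jitter one timestamp
  lines <- readLines(p)
  lines[10] <- sub("^8 ", "8.2 ", lines[10])
  writeLines(lines, p)
  expect_error(read_dipole_trajectory(p), "non-uniform")
})

test_that("stick spectra round-trip and reject negative intensities", {
  st <- stick_spectrum(c(500, 1000), c(10, 0))
  p <- withr::local_tempfile(fileext = ".dat")
  write_stick_spectrum(st, p)
  st2 <- read_stick_spectrum(p)
  expect_equal(st2$frequency, st$frequency)
  expect_equal(st2$intensity, st$intensity)
  writeLines(c("500 10", "1000 -3"), p)
  expect_error(read_stick_spectrum(p), "non-negative")
})

test_that("ion-count tables round-trip exactly", {
  d <- ion_counts(nu = c(500, 600), p_on = c(800, 700), f_on = c(200, 300),
                  p_off = c(900, 850), f_off = c(100, 150),
                  phi_tau = c(1, 1.5))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_ion_counts(d, p)
  d2 <- read_ion_counts(p)
  expect_equal(as.data.frame(d2), as.data.frame(d))
})
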
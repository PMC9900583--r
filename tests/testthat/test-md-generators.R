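# Velocity-Verlet engine, velocity initialisation, momentum projection,
# and the synthetic-data generators.

test_that("velocity init: zero at T = 0, equipartition at 2T, seeded", {
  expect_equal(init_velocities(c(1, 12), 0), matrix(0, 2, 3))
  m <- rep(c(1, 12, 16), length.out = 9999)
  v <- init_velocities(m, 300, seed = 4)
  ke <- sum(m * v^2) / 2 / length(m)
  want <- 1.5 * phys_const$kB_amu_A2_fs2 * 600  # 3/2 kB (2T) per atom
  expect_equal(ke, want, tolerance = 0.02)
  expect_identical(init_velocities(m, 300, seed = 4), v)
  expect_false(identical(init_velocities(m, 300, seed = 5), v))
})

test_that("momentum projection removes drift and rigid rotation", {
  set.seed(8)
  x <- matrix(rnorm(15, sd = 2), 5, 3)
  m <- runif(5, 1, 16)
  # uniform drift
  v_d <- matrix(rep(c(1, -2, 0.5), each = 5), 5, 3)
  expect_equal(remove_momenta(x, v_d, m), matrix(0, 5, 3),
               tolerance = 1e-12)
  # rigid rotation about the COM
  com <- colSums(x * m) / sum(m)
  om <- c(0.3, -0.1, 0.2)
  v_r <- t(apply(sweep(x, 2, com), 1, function(r)
    conformIR:::cross3(om, r)))
  expect_equal(remove_momenta(x, v_r, m), matrix(0, 5, 3),
               tolerance = 1e-10)
  # mixed field: residual momenta vanish
  v <- matrix(rnorm(15), 5, 3) + v_d + v_r
  v2 <- remove_momenta(x, v, m)
  p <- colSums(m * v2)
  L <- colSums(t(vapply(1:5, function(i)
    m[i] * conformIR:::cross3(sweep(x, 2, com)[i, ], v2[i, ]),
    numeric(3))))
  expect_lt(max(abs(p)), 1e-12 * max(abs(m * v2)))
  expect_lt(max(abs(L)), 1e-10)
})

test_that("a resting oscillator at its centre keeps a constant dipole", {
  sys <- harmonic_mode_system(1000, displacement = 0)
  tr <- simulate_md(sys, sim_config(steps = 200, init = "none"))
  expect_equal(max(tr$mu) - min(tr$mu), 0)
})

test_that("simulated harmonic modes oscillate at the integrator frequency", {
  for (cfg in list(c(800, 1), c(1400, 2))) {
    tr <- simulate_md(harmonic_mode_system(cfg[1]),
                      sim_config(dt_fs = cfg[2], steps = 4000,
                                 init = "none"))
    sp <- psd(tr)
    dnu <- sp$frequency[2] - sp$frequency[1]
    expect_lt(abs(psd_peak_frequency(tr) -
                    analytic_vv_frequency(cfg[1], cfg[2])), dnu)
  }
})

test_that("velocity Verlet shows bounded fluctuation and no energy drift", {
  # gentle regime: fluctuation well under 1e-4
  tr <- simulate_md(harmonic_mode_system(500),
                    sim_config(dt_fs = 0.1, steps = 20000, init = "none"))
  en <- attr(tr, "energy")
  expect_lt((max(en) - min(en)) / mean(en), 1e-4)
  # long run at 0.5 fs: fluctuation scales as (omega dt)^2, no secular drift
  tr2 <- simulate_md(harmonic_mode_system(1000),
                     sim_config(dt_fs = 0.5, steps = 100000, init = "none"))
  en2 <- attr(tr2, "energy")
  omdt <- 2 * pi * phys_const$c_cm_fs * 1000 * 0.5
  expect_lt((max(en2) - min(en2)) / mean(en2), omdt^2)
  n <- length(en2)
  first <- mean(en2[1:(n %/% 10)])
  last <- mean(en2[(n - n %/% 10):n])
  expect_equal(last, first, tolerance = 1e-6)
})

test_that("unstable configurations raise an instability error", {
  # omega dt = 2.4 > 2: divergent
  nu_bad <- 2.2 / (2 * pi * phys_const$c_cm_fs * 1)
  sys <- harmonic_mode_system(nu_bad)
  expect_error(simulate_md(sys, sim_config(dt_fs = 1, steps = 2000,
                                           init = "none")),
               "instability")
  expect_error(analytic_vv_frequency(nu_bad, 1), "unstable")
})

test_that("analytic integrator frequency matches its closed form", {
  expect_equal(analytic_vv_frequency(1000, 2), 1006.0, tolerance = 0.05)
  expect_equal(analytic_vv_frequency(1000, 1e-6), 1000, tolerance = 1e-9)
  # leading-order shift is quadratic in dt
  s2 <- analytic_vv_frequency(1000, 2) - 1000
  s1 <- analytic_vv_frequency(1000, 1) - 1000
  expect_equal(s2 / s1, 4, tolerance = 0.02)
})

test_that("pairwise potentials conserve energy too", {
  # two atoms on a spring: a stretched dimer
  sys <- model_system(masses = c(1, 1),
                      coords = rbind(c(0, 0, 0), c(1.2, 0, 0)),
                      charges = c(0.5, -0.5),
                      potential = list(type = "pair_spring",
                                       pairs = c(1, 2, 0.05, 1.0)))
  tr <- simulate_md(sys, sim_config(dt_fs = 0.25, steps = 5000,
                                    init = "none"))
  en <- attr(tr, "energy")
  expect_lt((max(en) - min(en)) / mean(en), 5e-3)
  # Morse dimer stays bound and conserves energy
  sysm <- model_system(masses = c(1, 1),
                       coords = rbind(c(0, 0, 0), c(1.1, 0, 0)),
                       charges = c(0.5, -0.5),
                       potential = list(type = "morse",
                                        pairs = c(1, 2, 0.02, 1.5, 1.0)))
  trm <- simulate_md(sysm, sim_config(dt_fs = 0.25, steps = 5000,
                                      init = "none"))
  enm <- attr(trm, "energy")
  expect_lt((max(enm) - min(enm)) / mean(enm), 1e-2)
})

test_that("dipole generator enforces Nyquist and is seed-deterministic", {
  expect_error(gen_dipole_signal(data.frame(nu = 4e4, amplitude = 1),
                                 dt_fs = 0.5, n = 128), "Nyquist")
  t1 <- gen_dipole_signal(data.frame(nu = 700, amplitude = 1), 1, 256,
                          noise_sd = 0.1, seed = 3)
  t2 <- gen_dipole_signal(data.frame(nu = 700, amplitude = 1), 1, 256,
                          noise_sd = 0.1, seed = 3)
  expect_identical(t1$mu, t2$mu)
})

test_that("pure noise has no stable peak across seeds", {
  peaks <- vapply(1:8, function(seed) {
    tr <- gen_dipole_signal(data.frame(nu = numeric(0),
                                       amplitude = numeric(0)),
                            dt_fs = 1, n = 512, noise_sd = 1, seed = seed)
    psd_peak_frequency(tr)
  }, numeric(1))
  expect_gt(length(unique(round(peaks))), 4L)
})

test_that("density-grid generator is deterministic and atom-centred", {
  s <- nho_triad()
  f <- gen_density_grid(s)
  f2 <- gen_density_grid(s)
  expect_identical(f$values, f2$values)
  # density at an atom centre is near the atom amplitude
  expect_equal(field_at(f, s$coords[1, , drop = FALSE]), 300,
               tolerance = 10)
})

test_that("ion-count generator matches its own model", {
  # no fragmentation: off-shot fragments are identically zero
  d0 <- gen_ion_counts(nu = c(500, 1000), sigma = c(0.1, 0.2),
                       frag_fraction = 0, n = 1e4, seed = 1)
  expect_equal(d0$f_off, c(0, 0))
  # sigma = 0: on and off ratios agree in expectation
  dflat <- gen_ion_counts(nu = seq(500, 1500, 100), sigma = 0,
                          frag_fraction = 0.2, n = 1e6, seed = 2)
  expect_equal(mean(dflat$p_on / (dflat$p_on + dflat$f_on)),
               mean(dflat$p_off / (dflat$p_off + dflat$f_off)),
               tolerance = 2e-3)
  expect_identical(gen_ion_counts(1000, 0.1, seed = 9)$p_on,
                   gen_ion_counts(1000, 0.1, seed = 9)$p_on)
})
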
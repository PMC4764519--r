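ff <- forcefield_params()

test_that("zero temperature, zero friction reduces to energy-conserving MD", {
  pos <- matrix(c(0, 0, 0, 0.43, 0, 0), 2, 3, byrow = TRUE)
  topo <- npcbarrier:::bare_topology(pos)
  topo$bonds <- matrix(c(1, 2), 1)
  topo$bond_k <- 8000; topo$bond_r0 <- 0.38
  topo$exclusions <- matrix(c(1, 2), 1)
  topo$vel <- matrix(0, 2, 3)
  ld <- langevin_params(temperature = 0, timestep = 0.001, friction = 0, seed = 1)
  e0 <- compute_energy(topo, ff)$total
  run <- run_dynamics(topo, ff, ld, n_steps = 1e4, sample_every = 10)
  efin <- compute_energy(run$topology, ff)$total + utils::tail(run$ke, 1)
  expect_lt(abs(efin - e0) / e0, 1e-4)
})

test_that("free-bead velocity variance satisfies equipartition within 2%", {
  topo <- npcbarrier:::bare_topology(matrix(0, 1, 3))
  ld <- langevin_params(300, 0.02, 5, seed = 11)
  run <- run_dynamics(topo, ff, ld, n_steps = 1e6, sample_every = 10)
  vv <- apply(run$vseries, 2, stats::var)
  expect_equal(mean(vv), kBT(300) / 120, tolerance = 0.02)
  ## mean kinetic energy per degree of freedom = kBT/2 within 2%
  expect_equal(mean(run$ke) / run$dof, kBT(300) / 2, tolerance = 0.02)
})

test_that("runs are reproducible and n_steps = 0 returns the initial frame", {
  topo <- random_chain_topology(5, seed = 2)
  ld <- langevin_params(300, 0.02, 10, seed = 7)
  r1 <- run_dynamics(topo, ff, ld, n_steps = 300, sample_every = 10)
  r2 <- run_dynamics(topo, ff, ld, n_steps = 300, sample_every = 10)
  expect_identical(r1$series, r2$series)
  expect_identical(r1$topology$pos, r2$topology$pos)
  r0 <- run_dynamics(topo, ff, ld, n_steps = 0, traj_every = 5)
  expect_equal(length(r0$frames), 1)
  expect_equal(r0$frames[[1]], topo$pos)
})

test_that("rigid cargo preserves inter-spot distances to 1e-9 nm", {
  topo <- add_cargo(empty_topology(), make_kap_complex(10, 7, 1.3),
                    center = c(0, 0, 0))
  spots <- which(topo$kind == 1)
  d0 <- dist(topo$pos[spots, ])
  ld <- langevin_params(300, 0.02, 1, seed = 3)
  run <- run_dynamics(topo, ff, ld, n_steps = 2000, sample_every = 100)
  d1 <- dist(run$topology$pos[spots, ])
  expect_lt(max(abs(d1 - d0)), 1e-9)
  ## and the quaternion stays normalised
  expect_equal(sum(run$topology$cargo$quat^2), 1, tolerance = 1e-9)
})

test_that("harmonically trapped cargo samples the Boltzmann distribution", {
  topo <- free_particle(D = 2)
  run <- run_dynamics(topo, ff, langevin_params(300, 0.02, 2, seed = 5),
                      restraints = list(restraint_harmonic3d(10)),
                      n_steps = 6e5, sample_every = 20)
  v <- c(stats::var(run$series$x), stats::var(run$series$y),
         stats::var(run$series$z))
  expect_equal(mean(v), kBT(300) / 10, tolerance = 0.05)
  expect_equal(mean(run$series$z), 0, tolerance = 3 * sqrt(kBT(300) / 10 / 100))
})

test_that("anchored beads never move", {
  geom <- scaffold_geometry(pore_diameter = 16, pore_half_height = 4)
  seqs <- c(s = "FSFGSTNQSA")
  anchors <- nup_anchors("NupX", 0, 8, 8L, "s")
  topo <- graft_nups(build_scaffold(geom), anchors, seqs, seed = 1, geom = geom)
  fixed <- which(topo$mobile == 0)
  run <- run_dynamics(topo, ff, langevin_params(300, 0.02, 5, seed = 2),
                      n_steps = 500, sample_every = 100)
  expect_identical(unname(run$topology$pos[fixed, ]),
                   unname(topo$pos[fixed, ]))
})

test_that("non-finite forces abort with a diagnostic", {
  topo <- npcbarrier:::bare_topology(matrix(0, 2, 3))
  topo$pos[2, ] <- c(NaN, 0, 0)
  topo$bonds <- matrix(c(1, 2), 1)
  topo$bond_k <- 8000; topo$bond_r0 <- 0.38
  expect_error(
    run_dynamics(topo, ff, langevin_params(300, 0.02, 1, seed = 1),
                 n_steps = 10, sample_every = 1),
    "non-finite")
})
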